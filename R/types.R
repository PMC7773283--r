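## Core domain types: axial grids/profiles, catheter specs, waveforms,
## fluid properties. All constructors validate; downstream code can
## assume the invariants hold.

#' Construct an axial grid
#'
#' A uniform grid of axial positions along the spine, in millimetres,
#' with \code{z = 0} at the foramen magnum and z increasing caudally.
#' The last grid point is the thecal-sac termination, so the total SAS
#' length \code{L_sas} equals \code{z[length(z)]}.
#'
#' @param z Numeric vector of axial positions (mm); must start at 0, be
#'   strictly increasing and uniformly spaced.
#' @return An object of class \code{axial_grid} with elements \code{z},
#'   \code{dz} (spacing, mm) and \code{L_sas} (mm).
#' @examples
#' g <- axial_grid(seq(0, 300, by = 1))
#' g$dz
#' g$L_sas
#' @export
axial_grid <- function(z) {
  z <- as.numeric(z)
  if (length(z) < 2L) stop("axial grid needs at least 2 points", call. = FALSE)
  if (anyNA(z) || any(!is.finite(z))) stop("axial grid positions must be finite", call. = FALSE)
  if (abs(z[1L]) > 1e-9) stop("axial grid must start at z = 0 (foramen magnum)", call. = FALSE)
  dzs <- diff(z)
  if (any(dzs <= 0)) stop("axial grid positions must be strictly increasing", call. = FALSE)
  dz <- mean(dzs)
  if (max(abs(dzs - dz)) > 1e-9 * max(dz, 1)) {
    stop("axial grid must be uniformly spaced", call. = FALSE)
  }
  structure(list(z = z, dz = dz, L_sas = z[length(z)]), class = "axial_grid")
}

#' Construct an axial geometric profile
#'
#' Per-position cross-sectional areas and perimeters of the spinal cord
#' and dura along the spine. Derived SAS quantities (\code{A_sas},
#' \code{P_sas}, \code{D_h}) are filled in by
#' [derive_sas_profile()], optionally with a catheter footprint.
#'
#' @param grid An [axial_grid()].
#' @param A_c,A_d Cord and dura cross-sectional areas (mm^2).
#' @param P_c,P_d Cord and dura perimeters (mm).
#' @param A_sas,P_sas,D_h Optional derived SAS area (mm^2), wetted
#'   perimeter (mm) and hydraulic diameter (mm).
#' @return An object of class \code{axial_profile}.
#' @export
axial_profile <- function(grid, A_c, A_d, P_c, P_d,
                          A_sas = NULL, P_sas = NULL, D_h = NULL) {
  stopifnot(inherits(grid, "axial_grid"))
  n <- length(grid$z)
  for (nm in c("A_c", "A_d", "P_c", "P_d")) {
    v <- get(nm)
    if (length(v) == 1L) assign(nm, rep(as.numeric(v), n))
    v <- get(nm)
    if (length(v) != n) stop(sprintf("%s must have one value per grid point", nm), call. = FALSE)
    if (anyNA(v) || any(!is.finite(v))) stop(sprintf("%s must be finite", nm), call. = FALSE)
  }
  if (any(A_c < 0)) stop("cord area A_c must be non-negative", call. = FALSE)
  if (any(A_d <= A_c)) {
    bad <- grid$z[which(A_d <= A_c)[1L]]
    stop(sprintf("dura area must exceed cord area everywhere (violated at z = %g mm)", bad),
         call. = FALSE)
  }
  if (any(P_c < 0) || any(P_d < 0)) stop("perimeters must be non-negative", call. = FALSE)
  structure(list(grid = grid, A_c = as.numeric(A_c), A_d = as.numeric(A_d),
                 P_c = as.numeric(P_c), P_d = as.numeric(P_d),
                 A_sas = A_sas, P_sas = P_sas, D_h = D_h),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("<axial_profile> %d points, dz = %g mm, L_sas = %g mm, %s\n",
              length(x$grid$z), x$grid$dz, x$grid$L_sas,
              if (is.null(x$A_sas)) "raw" else "derived"))
  invisible(x)
}

#' Construct an intrathecal catheter specification
#'
#' The catheter runs from its entry site (caudal, larger z) to its tip
#' (rostral, smaller z). Segments are listed from the tip toward the
#' entry site, each with a length, outer diameter (OD) and inner
#' diameter (ID) in mm. The default is a three-segment infusion
#' catheter: 100 mm distal to the tip (OD 0.99, ID 0.38), then 240 mm
#' (OD 1.98, ID 1.19), then 15 mm (OD 1.93, ID 1.07).
#'
#' @param tip_z Axial position of the catheter tip (mm).
#' @param entry_z Axial position of the dural entry site (mm); must be
#'   caudal to (greater than) \code{tip_z}.
#' @param segments Data frame with columns \code{length}, \code{od},
#'   \code{id} (all mm), ordered from the tip.
#' @return An object of class \code{catheter_spec}.
#' @export
catheter_spec <- function(tip_z, entry_z,
                          segments = default_catheter_segments()) {
  stopifnot(is.numeric(tip_z), is.numeric(entry_z))
  if (entry_z < tip_z) stop("entry_z must be caudal to (>=) tip_z", call. = FALSE)
  segments <- as.data.frame(segments)
  if (!all(c("length", "od", "id") %in% names(segments))) {
    stop("segments need columns length, od, id", call. = FALSE)
  }
  if (any(segments$length <= 0)) stop("segment lengths must be positive", call. = FALSE)
  if (any(segments$id <= 0) || any(segments$od <= segments$id)) {
    stop("segment diameters must satisfy OD > ID > 0", call. = FALSE)
  }
  structure(list(tip_z = as.numeric(tip_z), entry_z = as.numeric(entry_z),
                 segments = segments),
            class = "catheter_spec")
}

#' Default catheter segment table
#'
#' @return Data frame of the default three-segment catheter geometry,
#'   ordered from the tip (lengths 100, 240, 15 mm).
#' @export
default_catheter_segments <- function() {
  data.frame(length = c(100, 240, 15),
             od     = c(0.99, 1.98, 1.93),
             id     = c(0.38, 1.19, 1.07))
}

#' Construct a cardiac-gated flow waveform
#'
#' Volumetric CSF flow \code{Q(t)} (mL/s) over one cardiac cycle at one
#' axial level. Caudally directed (systolic) flow is negative.
#'
#' @param level_z Axial position of the measurement slice (mm).
#' @param t Sample times (s) within \code{[0, T)}, strictly increasing.
#' @param Q Flow samples (mL/s), same length as \code{t}.
#' @param T Cardiac period (s). If missing, inferred as the time range
#'   plus one sample step.
#' @return An object of class \code{flow_waveform}.
#' @export
flow_waveform <- function(level_z, t, Q, T = NULL) {
  t <- as.numeric(t); Q <- as.numeric(Q)
  if (length(t) != length(Q)) stop("t and Q must have equal length", call. = FALSE)
  if (length(t) < 2L) stop("waveform needs at least 2 time samples", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (anyNA(Q) || any(!is.finite(Q))) stop("Q must be finite", call. = FALSE)
  if (is.null(T)) T <- diff(range(t)) + mean(diff(t))
  T <- as.numeric(T)
  if (T <= 0) stop("cardiac period T must be positive", call. = FALSE)
  if (t[1L] < 0 || t[length(t)] >= T) {
    stop("t must lie within [0, T)", call. = FALSE)
  }
  structure(list(level_z = as.numeric(level_z), t = t, Q = Q, T = T),
            class = "flow_waveform")
}

#' CSF fluid properties
#'
#' Kinematic viscosity of CSF at body temperature and the reference
#' cardiac period used for cycle normalization and for the angular
#' frequency \eqn{\omega = 2\pi/T_{ref}}.
#'
#' @param nu Kinematic viscosity (mm^2/s); default 0.693.
#' @param T_ref Reference cardiac period (s); default 0.53.
#' @return An object of class \code{fluid_properties} with elements
#'   \code{nu}, \code{T_ref} and \code{omega} (rad/s).
#' @export
fluid_properties <- function(nu = 0.693, T_ref = 0.53) {
  if (nu <= 0) stop("kinematic viscosity nu must be positive", call. = FALSE)
  if (T_ref <= 0) stop("reference cardiac period must be positive", call. = FALSE)
  structure(list(nu = nu, T_ref = T_ref, omega = 2 * pi / T_ref),
            class = "fluid_properties")
}

#' Nerve-root cylinder model
#'
#' Diameter of the nerve-root "cylinder" used in the external-flow
#' Reynolds and Keulegan-Carpenter numbers. Anatomical nerve-root
#' diameters in cynomolgus monkeys span roughly 0.2 to 0.3 mm; the
#' default is a constant 0.25 mm, and an axial profile may be supplied.
#'
#' @param D_NR Nerve-root diameter (mm); scalar or a vector matching the
#'   axial grid it will be used on.
#' @return An object of class \code{nerve_root_model}.
#' @export
nerve_root_model <- function(D_NR = 0.25) {
  D_NR <- as.numeric(D_NR)
  if (any(D_NR <= 0)) stop("nerve-root diameter must be positive", call. = FALSE)
  structure(list(D_NR = D_NR), class = "nerve_root_model")
}

#' Subject record
#'
#' Metadata for one study animal: implantation group, scan timepoint
#' vocabulary, body weight, age and mean heart period.
#'
#' @param id Subject identifier.
#' @param group \code{"cervical"} or \code{"lumbar"}.
#' @param weight Body weight (kg), positive.
#' @param age Age (years), positive.
#' @param T Mean cardiac period (s), positive.
#' @return An object of class \code{subject_record}.
#' @export
subject_record <- function(id, group, weight, age, T = 0.53) {
  group <- match.arg(group, c("cervical", "lumbar"))
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive", call. = FALSE)
  if (!is.finite(age) || age <= 0) stop("age must be positive", call. = FALSE)
  if (!is.finite(T) || T <= 0) stop("heart period must be positive", call. = FALSE)
  structure(list(id = as.character(id), group = group,
                 weight = weight, age = age, T = T),
            class = "subject_record")
}

#' Timepoint vocabulary for implantation studies
#' @return Character vector of the recognised scan timepoints.
#' @export
timepoint_levels <- function() c("PRE-2", "POST-1", "POST-2")
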