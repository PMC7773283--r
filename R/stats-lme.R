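## Linear mixed-effects comparison battery. Each parameter's axial
## distribution is modelled as
##   y = b0 + b1 x1 + b2 x1^2 + b3 x2 + b4 x3 + b5 x4
##       + z0 + z1 x1 + z2 x1^2 + eps
## with x1 the normalized axial location, x2 the 0/1 comparison
## indicator (catheter location or scan timepoint), x3 age, x4 weight,
## and per-subject random intercept/linear/quadratic location terms
## with unstructured 3x3 covariance. The battery runs this model for
## 13 parameters x 7 comparisons and Bonferroni-corrects the 91 Wald
## p-values for the comparison coefficient b3.

#' The 13 battery parameters
#' @return Character vector of parameter names in battery order.
#' @export
battery_parameters <- function() {
  c("A_d", "A_c", "A_sas", "P_d", "P_c", "P_sas", "D_h",
    "alpha", "Re", "U_peak_sys", "U_peak_dia", "Q_a", "SV")
}

#' The 7 battery comparisons
#'
#' Four pairs compare scan timepoints within an implantation group
#' (PRE-2 vs POST-1 and PRE-2 vs POST-2, cervical and lumbar), and
#' three compare cervical versus lumbar implantation at each timepoint.
#' In each pair the first-listed cell is the reference (\code{x2 = 0}).
#'
#' @return Named list of comparisons, each with cells \code{a} and
#'   \code{b} (group/timepoint restrictions).
#' @export
battery_comparisons <- function() {
  cell <- function(group, timepoint) list(group = group, timepoint = timepoint)
  list(
    "PRE-2C vs POST-1C" = list(a = cell("cervical", "PRE-2"), b = cell("cervical", "POST-1")),
    "PRE-2L vs POST-1L" = list(a = cell("lumbar", "PRE-2"),  b = cell("lumbar", "POST-1")),
    "PRE-2C vs POST-2C" = list(a = cell("cervical", "PRE-2"), b = cell("cervical", "POST-2")),
    "PRE-2L vs POST-2L" = list(a = cell("lumbar", "PRE-2"),  b = cell("lumbar", "POST-2")),
    "PRE-2C vs PRE-2L"  = list(a = cell("cervical", "PRE-2"), b = cell("lumbar", "PRE-2")),
    "POST-1C vs POST-1L" = list(a = cell("cervical", "POST-1"), b = cell("lumbar", "POST-1")),
    "POST-2C vs POST-2L" = list(a = cell("cervical", "POST-2"), b = cell("lumbar", "POST-2")))
}

#' Assemble the long-format parameter table
#'
#' Combines per-subject axial parameter values with subject metadata
#' into the long table the mixed model consumes. The axial coordinate
#' is rescaled to \code{[0, 1]} (better conditioning of the quadratic
#' term). Rows with missing values are dropped with a message; exact
#' duplicates of (subject, timepoint, z, parameter) are an error.
#'
#' @param values Data frame with columns \code{id}, \code{timepoint},
#'   \code{z} (mm, on the common normalized grid), \code{parameter},
#'   \code{value}.
#' @param metadata Data frame with columns \code{id}, \code{group},
#'   \code{age} (yr), \code{weight} (kg).
#' @return A data frame of class \code{long_table} with columns
#'   \code{id}, \code{group}, \code{timepoint}, \code{x1} (normalized
#'   location), \code{x3} (age), \code{x4} (weight), \code{parameter},
#'   \code{y}.
#' @export
assemble_long_table <- function(values, metadata) {
  values <- as.data.frame(values); metadata <- as.data.frame(metadata)
  need_v <- c("id", "timepoint", "z", "parameter", "value")
  need_m <- c("id", "group", "age", "weight")
  if (!all(need_v %in% names(values))) {
    stop(sprintf("values need columns: %s", paste(need_v, collapse = ", ")), call. = FALSE)
  }
  if (!all(need_m %in% names(metadata))) {
    stop(sprintf("metadata need columns: %s", paste(need_m, collapse = ", ")), call. = FALSE)
  }
  miss_meta <- setdiff(unique(values$id), metadata$id)
  if (length(miss_meta)) {
    stop(sprintf("no metadata for subject(s): %s", paste(miss_meta, collapse = ", ")),
         call. = FALSE)
  }
  bad <- metadata$id[!is.finite(metadata$age) | !is.finite(metadata$weight) |
                       metadata$age <= 0 | metadata$weight <= 0]
  if (length(bad)) {
    stop(sprintf("missing/invalid age or weight for subject(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  key <- interaction(values$id, values$timepoint, values$z, values$parameter, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, timepoint, z, parameter) rows", call. = FALSE)
  }
  n_na <- sum(!is.finite(values$value))
  if (n_na > 0L) {
    message(sprintf("dropping %d rows with missing values", n_na))
    values <- values[is.finite(values$value), ]
  }
  m <- metadata[match(values$id, metadata$id), ]
  z_max <- max(values$z)
  out <- data.frame(id = as.character(values$id),
                    group = as.character(m$group),
                    timepoint = as.character(values$timepoint),
                    x1 = values$z / z_max,
                    x3 = m$age, x4 = m$weight,
                    parameter = as.character(values$parameter),
                    y = values$value)
  attr(out, "z_max") <- z_max
  class(out) <- c("long_table", "data.frame")
  out
}

match_cell <- function(table, cell) {
  table$group == cell$group & table$timepoint == cell$timepoint
}

#' Fit the mixed model for one parameter and one comparison
#'
#' Restricts the long table to one parameter and the two cells of a
#' comparison, codes the indicator \code{x2} as 0 (reference cell) / 1,
#' and fits by restricted maximum likelihood with \pkg{lme4}:
#' \code{y ~ x1 + I(x1^2) + x2 + x3 + x4 + (1 + x1 + I(x1^2) | id)}.
#' The p-value for the comparison coefficient is a Wald z-test. A
#' singular unstructured random-effect covariance triggers a flagged
#' refit with independent (diagonal) random effects; non-convergence is
#' flagged rather than raised.
#'
#' @param table A \code{long_table} from [assemble_long_table()].
#' @param parameter Parameter name to model.
#' @param comparison One element of [battery_comparisons()] (or any
#'   list with cells \code{a} and \code{b}).
#' @return An object of class \code{lme_fit}: fixed effects
#'   (\code{beta}, \code{se}), \code{p_x2}, random-effect covariance
#'   \code{vcov_random}, residual \code{sigma}, \code{logLik},
#'   \code{n_subjects}, and flags \code{converged}/\code{singular}/
#'   \code{diagonal_refit}.
#' @export
fit_lme <- function(table, parameter, comparison) {
  stopifnot(inherits(table, "long_table"))
  d <- table[table$parameter == parameter & (match_cell(table, comparison$a) |
                                               match_cell(table, comparison$b)), ]
  if (nrow(d) == 0L) stop(sprintf("no rows for parameter %s", parameter), call. = FALSE)
  d$x2 <- as.numeric(match_cell(d, comparison$b))
  if (length(unique(d$x2)) < 2L) {
    stop("comparison indicator x2 is constant; the two cells must differ", call. = FALSE)
  }
  for (lvl in c(0, 1)) {
    ns <- length(unique(d$id[d$x2 == lvl]))
    if (ns < 2L) stop("need >= 2 subjects in each comparison cell", call. = FALSE)
  }
  d$x1sq <- d$x1^2
  fit_once <- function(form) {
    warn <- character()
    f <- withCallingHandlers(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = TRUE)),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    list(fit = f, warnings = warn)
  }
  r <- fit_once(y ~ x1 + x1sq + x2 + x3 + x4 + (1 + x1 + x1sq | id))
  singular <- lme4::isSingular(r$fit, tol = 1e-4)
  diagonal_refit <- FALSE
  if (singular) {
    r <- fit_once(y ~ x1 + x1sq + x2 + x3 + x4 +
                    (1 | id) + (0 + x1 | id) + (0 + x1sq | id))
    diagonal_refit <- TRUE
  }
  fit <- r$fit
  converged <- length(r$warnings) == 0L &&
    is.null(fit@optinfo$conv$lme4$code)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  if (!"x2" %in% names(fe)) {
    stop("comparison coefficient is inestimable (rank-deficient design)", call. = FALSE)
  }
  zval <- fe[["x2"]] / se[["x2"]]
  p_x2 <- 2 * pnorm(-abs(zval))
  vc <- lme4::VarCorr(fit)
  vcov_random <- if (!diagonal_refit) {
    m <- as.matrix(Matrix::bdiag(lapply(vc, function(v) v[, , drop = FALSE])))
    m
  } else {
    diag(vapply(vc, function(v) as.numeric(v[1L, 1L]), numeric(1)))
  }
  structure(list(beta = fe, se = se, p_x2 = unname(p_x2), z_x2 = unname(zval),
                 vcov_random = vcov_random, sigma = stats::sigma(fit),
                 logLik = as.numeric(logLik(fit)),
                 n_subjects = length(unique(d$id)), n_rows = nrow(d),
                 converged = converged, singular = singular,
                 diagonal_refit = diagonal_refit, warnings = r$warnings,
                 parameter = parameter),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("<lme_fit> %s: b3 = %.4g (SE %.3g), Wald p = %.3g%s%s\n",
              x$parameter, x$beta[["x2"]], x$se[["x2"]], x$p_x2,
              if (x$diagonal_refit) " [diagonal refit]" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Run the full comparison battery
#'
#' Fits [fit_lme()] for every parameter x comparison pair, collects the
#' Wald p-values for the comparison coefficient, and applies a
#' Bonferroni threshold of \code{alpha} divided by the number of tests
#' (0.05/91 = 5.49e-4 for the default 13 x 7 grid). Significance stars
#' follow graded Bonferroni levels: \code{*} p < 0.05/n, \code{**}
#' p < 0.01/n, \code{***} p < 0.005/n, \code{****} p < 0.001/n.
#' Non-converging fits are recorded as \code{NA} with a warning, never
#' silently dropped.
#'
#' @param table A \code{long_table} containing all 13 battery
#'   parameters.
#' @param alpha Family-wise error rate; default 0.05.
#' @param parameters,comparisons Battery definition; defaults to
#'   [battery_parameters()] and [battery_comparisons()].
#' @return An object of class \code{comparison_battery}: matrices
#'   \code{p} and \code{stars} (parameters x comparisons),
#'   \code{threshold}, \code{alpha}, \code{n_tests}, and the list of
#'   \code{fits}.
#' @export
run_battery <- function(table, alpha = 0.05,
                        parameters = battery_parameters(),
                        comparisons = battery_comparisons()) {
  stopifnot(inherits(table, "long_table"))
  absent <- setdiff(parameters, unique(table$parameter))
  if (length(absent)) {
    stop(sprintf("battery parameter(s) missing from the table: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  n_tests <- length(parameters) * length(comparisons)
  p <- matrix(NA_real_, length(parameters), length(comparisons),
              dimnames = list(parameters, names(comparisons)))
  fits <- list()
  for (pm in parameters) {
    for (cn in names(comparisons)) {
      f <- fit_lme(table, pm, comparisons[[cn]])
      fits[[paste(pm, cn, sep = " | ")]] <- f
      if (f$converged) {
        p[pm, cn] <- f$p_x2
      } else {
        warning(sprintf("fit did not converge for %s, %s; p recorded as NA", pm, cn))
      }
    }
  }
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  lv <- c(0.001, 0.005, 0.01, 0.05) / n_tests
  sym <- c("****", "***", "**", "*")
  for (i in seq_along(lv)) stars[!is.na(p) & p < lv[i] & stars == ""] <- sym[i]
  structure(list(p = p, stars = stars, threshold = alpha / n_tests,
                 alpha = alpha, n_tests = n_tests, fits = fits),
            class = "comparison_battery")
}

#' @export
print.comparison_battery <- function(x, ...) {
  cat(sprintf("<comparison_battery> %d tests, Bonferroni threshold %.3g\n",
              x$n_tests, x$threshold))
  print(x$stars, quote = FALSE)
  invisible(x)
}
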