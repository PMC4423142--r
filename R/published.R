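#' The published final QSAR equations
#'
#' The two final linear models for MMP-2 inhibitory activity (pIC50) of the
#' L-tyrosine inhibitor series, with coefficients at full printed
#' precision:
#' * `eq1_mlr` — the general stepwise-MLR model:
#'   `pIC50 = -13.428 + 5.965 IC1 + 1.464 Mor24m - 0.187 RDF115m
#'    + 0.307 SP20 + 1.284 Mor15e`
#'   (N = 24, R2_c = 0.958, S.E = 0.285, Q2_LOO = 0.921, RMS_CV = 0.346);
#' * `eq2_gapls` — the GA-PLS model:
#'   `pIC50 = -12.589 + 6.363 IC1 + 2.119 Mor24m - 0.665 Mor15e
#'    - 0.784 Mor32e`
#'   (N = 24, R2_c = 0.932, S.E = 0.328, Q2_LOO = 0.900, RMS_CV = 0.391).
#'
#' @param id `"eq1_mlr"` or `"eq2_gapls"`.
#' @return list of class `published_equation` with `id`, `intercept`,
#'   `coefficients` (named), `coef_se`, `stats`.
#' @export
published_equation <- function(id = c("eq1_mlr", "eq2_gapls")) {
  id <- match.arg(id)
  eq <- switch(id,
    eq1_mlr = list(
      intercept = -13.428, intercept_se = 1.720,
      coefficients = c(IC1 = 5.965, Mor24m = 1.464, RDF115m = -0.187,
                       SP20 = 0.307, Mor15e = 1.284),
      coef_se = c(IC1 = 0.488, Mor24m = 0.618, RDF115m = 0.044,
                  SP20 = 0.067, Mor15e = 0.514),
      stats = c(N = 24, R2_c = 0.958, S.E = 0.285, Q2_LOO = 0.921,
                RMS_CV = 0.346)),
    eq2_gapls = list(
      intercept = -12.589, intercept_se = 1.208,
      coefficients = c(IC1 = 6.363, Mor24m = 2.119, Mor15e = -0.665,
                       Mor32e = -0.784),
      coef_se = c(IC1 = 0.394, Mor24m = 0.485, Mor15e = 0.189,
                  Mor32e = 0.370),
      stats = c(N = 24, R2_c = 0.932, S.E = 0.328, Q2_LOO = 0.900,
                RMS_CV = 0.391)))
  structure(c(list(id = id), eq), class = "published_equation")
}

#' @export
print.published_equation <- function(x, ...) {
  terms <- sprintf("%+.3f %s", x$coefficients, names(x$coefficients))
  cat("<published_equation>", x$id, "\n  pIC50 =",
      sprintf("%.3f", x$intercept), paste(terms, collapse = " "), "\n  ")
  cat(paste(names(x$stats), "=", x$stats, collapse = ", "), "\n")
  invisible(x)
}

#' Predict pIC50 from a published equation
#'
#' Evaluates `intercept + sum(coefficient * descriptor)` with the printed
#' coefficients exactly. Descriptor values are matched by name; every
#' descriptor of the equation must be supplied.
#'
#' @param id `"eq1_mlr"` or `"eq2_gapls"`.
#' @param descriptors named numeric vector, named list, or data.frame/matrix
#'   with descriptor columns (one prediction per row).
#' @return numeric vector of predicted pIC50.
#' @export
predict_published <- function(id, descriptors) {
  eq <- published_equation(id)
  if (is.data.frame(descriptors) || is.matrix(descriptors)) {
    M <- as.matrix(descriptors)
    miss <- setdiff(names(eq$coefficients), colnames(M))
    if (length(miss))
      stop("missing descriptor(s): ", paste(miss, collapse = ", "))
    return(drop(M[, names(eq$coefficients), drop = FALSE] %*%
                  eq$coefficients) + eq$intercept)
  }
  v <- unlist(descriptors)
  miss <- setdiff(names(eq$coefficients), names(v))
  if (length(miss))
    stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  sum(eq$coefficients * v[names(eq$coefficients)]) + eq$intercept
}

#' Reference activity table of the L-tyrosine inhibitor series
#'
#' The 30 inhibitors with their R1/R2/R3 substituent labels, experimental
#' pIC50 and the activities predicted by the two published models. The
#' scaffold connectivity is not encoded (it is defined graphically in the
#' source); the table ships as labels + activities.
#'
#' @return data.frame with columns `compound`, `r1`, `r2`, `r3`,
#'   `pic50_exp`, `pic50_mlr`, `pic50_gapls` (30 rows).
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_tyrosine_mmp2.csv",
                      package = "tyroqsar")
  if (path == "") path <- file.path("inst", "extdata",
                                    "table1_tyrosine_mmp2.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
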