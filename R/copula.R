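#' Convert Kendall's tau to the Pearson correlation of a Gaussian copula
#'
#' Under a bivariate Gaussian copula, Kendall's tau and the latent Pearson
#' correlation are linked by Greiner's relation \eqn{\rho = \sin(\pi \tau / 2)}.
#' The cohort generator uses this map to hit Kendall-tau targets exactly in
#' distribution, for arbitrary continuous marginals.
#'
#' @param tau Kendall correlation(s) in \[-1, 1\].
#' @return Pearson correlation(s) in \[-1, 1\], strictly increasing in `tau`.
#' @seealso [pearson_to_tau()], [r_equivalent_threshold()]
#' @export
#' @examples
#' tau_to_pearson(c(0, 0.08, 1))
tau_to_pearson <- function(tau) {
  if (any(!is.finite(tau)) || any(abs(tau) > 1)) {
    stop_domain("`tau` must be finite and within [-1, 1]")
  }
  sin(pi * tau / 2)
}

#' Inverse of [tau_to_pearson()]
#'
#' @param rho Pearson correlation(s) in \[-1, 1\].
#' @return Kendall tau value(s).
#' @export
pearson_to_tau <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) > 1)) {
    stop_domain("`rho` must be finite and within [-1, 1]")
  }
  2 / pi * asin(rho)
}

#' Kendall-scale equivalent of a Pearson effect-size threshold
#'
#' The preregistered effect-size bound for the correlation analysis is stated
#' as a bivariate r-equivalent of 0.08. This converts such a Pearson-scale
#' threshold to the Kendall tau whose r-equivalent (under bivariate normality)
#' equals `r`: \eqn{\tau^* = (2/\pi) \arcsin(r)}.
#'
#' @param r Pearson-scale threshold, strictly inside (-1, 1).
#' @return The Kendall-scale threshold.
#' @export
#' @examples
#' r_equivalent_threshold(0.08)  # ~0.051
r_equivalent_threshold <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop_domain("`r` must be strictly inside (-1, 1)")
  }
  pearson_to_tau(r)
}

#' Build a validated Kendall-tau correlation target
#'
#' Checks symmetry and the unit diagonal, converts the tau matrix to the
#' latent Pearson scale, and — if the implied Pearson matrix is not positive
#' semi-definite — repairs it by nearest-PSD projection
#' ([Matrix::nearPD()]) with a warning.
#'
#' @param tau Symmetric numeric matrix of Kendall tau targets with unit
#'   diagonal; dimnames give the measure identifiers.
#' @return An object of class `corr_target`: list with `variables`, `tau`
#'   (possibly repaired, back-converted from the projected Pearson matrix),
#'   `rho` (latent Pearson matrix, PSD), and `repaired` flag.
#' @export
corr_target <- function(tau) {
  if (!is.matrix(tau) || nrow(tau) != ncol(tau)) {
    stop_domain("`tau` must be a square matrix")
  }
  if (is.null(rownames(tau))) {
    rownames(tau) <- colnames(tau) <- paste0("v", seq_len(nrow(tau)))
  }
  if (max(abs(tau - t(tau))) > 1e-10) stop_domain("`tau` must be symmetric")
  if (max(abs(diag(tau) - 1)) > 1e-10) stop_domain("`tau` must have a unit diagonal")
  rho <- tau_to_pearson(tau)
  repaired <- FALSE
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("implied Pearson matrix not positive semi-definite; ",
            "repaired by nearest-PSD projection", call. = FALSE)
    rho <- as.matrix(Matrix::nearPD(rho, corr = TRUE)$mat)
    dimnames(rho) <- dimnames(tau)
    tau <- pearson_to_tau(rho)
    diag(tau) <- 1
    repaired <- TRUE
  }
  structure(
    list(variables = rownames(tau), tau = tau, rho = rho, repaired = repaired),
    class = "corr_target"
  )
}
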