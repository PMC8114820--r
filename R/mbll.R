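#' Modified Beer-Lambert law parameters
#'
#' Holds the quantities needed to map two-wavelength optical-density changes
#' to hemoglobin concentration changes: the extinction coefficients of HbO
#' and HbR at each wavelength, the differential pathlength factor (DPF) per
#' wavelength, and the source-detector separation rho.
#'
#' The defaults (760/850 nm; extinction coefficients in 1/(mM*cm) from
#' standard tabulations; DPF 6 at both wavelengths; rho 3 cm) are common
#' continuous-wave fNIRS values.  They are configuration, not measurements:
#' any analysis that relies on absolute concentrations should substitute
#' instrument-specific values.
#'
#' @param lambda Length-2 wavelengths in nm.
#' @param eps 2x2 matrix of extinction coefficients in 1/(mM*cm); rows are
#'   wavelengths (in `lambda` order), columns are chromophores (HbO, HbR).
#' @param dpf Length-2 differential pathlength factors (dimensionless).
#' @param rho Source-detector separation in cm.
#'
#' @return Object of class `mbll_params` with the premultiplied system matrix
#'   `M[w, c] = eps[w, c] * dpf[w]`.
#' @examples
#' p <- mbll_params()
#' od <- mbll_forward(hbo = 0.01, hbr = -0.004, p)
#' mbll_inverse(od$od1, od$od2, p)
#' @export
mbll_params <- function(lambda = c(760, 850),
                        eps = matrix(c(0.5958, 1.6745,
                                       1.0507, 0.7861),
                                     nrow = 2, byrow = TRUE,
                                     dimnames = list(NULL, c("HbO", "HbR"))),
                        dpf = c(6, 6),
                        rho = 3) {
  if (length(lambda) != 2 || length(dpf) != 2)
    stop("exactly two wavelengths are required")
  if (!all(dim(eps) == c(2, 2)) || any(!is.finite(eps)))
    stop("eps must be a finite 2x2 matrix (rows wavelengths, cols HbO/HbR)")
  if (any(dpf <= 0) || rho <= 0) stop("dpf and rho must be > 0")
  M <- eps * dpf  # row scaling: eps[w, ] * dpf[w]
  if (!is.finite(rcond(M)) || rcond(M) < .Machine$double.eps * 100)
    stop("extinction/DPF system matrix is singular or near-singular")
  structure(list(lambda = lambda, eps = eps, dpf = dpf, rho = rho,
                 M = M, Minv = solve(M)),
            class = "mbll_params")
}

#' @export
print.mbll_params <- function(x, ...) {
  cat(sprintf("<mbll_params> lambda = %g/%g nm, DPF = %g/%g, rho = %g cm\n",
              x$lambda[1], x$lambda[2], x$dpf[1], x$dpf[2], x$rho))
  invisible(x)
}

check_mbll_lengths <- function(a, b) {
  if (length(a) != length(b))
    stop("the two series must have the same length")
}

#' Invert the modified Beer-Lambert law
#'
#' Maps optical-density changes at two wavelengths to oxy- and
#' deoxyhemoglobin concentration changes, samplewise:
#' `[dHbO; dHbR] = (1/rho) * M^{-1} [OD_l1; OD_l2]` with
#' `M[w, c] = eps_c(lambda_w) * DPF(lambda_w)`.
#'
#' @param od1,od2 Optical-density series (numeric vectors or matrices of
#'   identical shape) at the first and second wavelength.
#' @param p An [mbll_params] object.
#' @return List with components `hbo` and `hbr` (mM), same shape as input.
#' @seealso [mbll_forward()]
#' @export
mbll_inverse <- function(od1, od2, p = mbll_params()) {
  if (!inherits(p, "mbll_params")) stop("p must be an mbll_params object")
  check_mbll_lengths(od1, od2)
  A <- p$Minv / p$rho
  list(hbo = A[1, 1] * od1 + A[1, 2] * od2,
       hbr = A[2, 1] * od1 + A[2, 2] * od2)
}

#' Forward modified Beer-Lambert map
#'
#' Synthesizes two-wavelength optical-density changes from known hemoglobin
#' concentration changes; the exact linear inverse of [mbll_inverse()], used
#' by the synthetic generator and in round-trip tests.
#'
#' @param hbo,hbr Concentration-change series in mM (vectors or matrices of
#'   identical shape).
#' @inheritParams mbll_inverse
#' @return List with components `od1` and `od2`.
#' @export
mbll_forward <- function(hbo, hbr, p = mbll_params()) {
  if (!inherits(p, "mbll_params")) stop("p must be an mbll_params object")
  check_mbll_lengths(hbo, hbr)
  M <- p$M * p$rho
  list(od1 = M[1, 1] * hbo + M[1, 2] * hbr,
       od2 = M[2, 1] * hbo + M[2, 2] * hbr)
}

#' Convert an optical-density recording to hemoglobin recordings
#'
#' Applies [mbll_inverse()] to every source-detector pair of an
#' optical-density [bci_recording], producing one HbO and one HbR recording
#' whose channels are the pairs (markers and identifiers are inherited).
#'
#' @param rec A `bci_recording` with modality `"od"`.
#' @param p An [mbll_params] object; defaults to the parameters attached to
#'   the recording by the generator, if any.
#' @return List with `bci_recording` components `hbo` and `hbr`.
#' @export
od_to_hemo <- function(rec, p = NULL) {
  if (!inherits(rec, "bci_recording") || rec$modality != "od")
    stop("rec must be an optical-density bci_recording")
  if (is.null(p)) p <- attr(rec, "mbll") %||% mbll_params()
  pairs <- unique(rec$channels$pair_id)
  n <- length(pairs)
  hbo <- matrix(0, n, ncol(rec$data))
  hbr <- matrix(0, n, ncol(rec$data))
  for (k in seq_along(pairs)) {
    idx <- which(rec$channels$pair_id == pairs[k])
    idx <- idx[order(rec$channels$wavelength[idx])]  # lambda1 first
    conc <- mbll_inverse(rec$data[idx[1], ], rec$data[idx[2], ], p)
    hbo[k, ] <- conc$hbo
    hbr[k, ] <- conc$hbr
  }
  ch <- function(mod) data.frame(id = paste0(mod, "_", pairs),
                                 modality = mod, wavelength = NA_real_,
                                 pair_id = pairs,
                                 rho = p$rho, stringsAsFactors = FALSE)
  list(hbo = bci_recording(hbo, rec$fs, ch("hbo"), rec$markers,
                           rec$subject_id, rec$session_id, "hbo"),
       hbr = bci_recording(hbr, rec$fs, ch("hbr"), rec$markers,
                           rec$subject_id, rec$session_id, "hbr"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
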