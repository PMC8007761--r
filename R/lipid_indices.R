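#' Derived lipid indices
#'
#' Computes the six derived lipid parameters from a standard lipid panel:
#' \itemize{
#'   \item non-HDL-C: \code{tc - hdl} (mmol/L)
#'   \item atherosclerosis index (AI): \code{(tc - hdl) / hdl}
#'   \item atherogenic index of plasma (AIP): \code{log10(tg / hdl)}
#'   \item lipoprotein combine index (LCI): \code{tc * tg * ldl / hdl}
#'   \item LDL-C/HDL-C ratio: \code{ldl / hdl}
#'   \item apoB/apoA-I ratio: \code{apob / apoa1} (NA when either is absent)
#' }
#' All inputs in mmol/L except the apolipoproteins (g/L). A negative
#' non-HDL-C (tc < hdl) is biologically implausible but arithmetically
#' defined; it is returned with a warning rather than an error so noisy
#' synthetic panels do not abort a pipeline run.
#'
#' @param tc total cholesterol, mmol/L.
#' @param tg triglyceride, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @param ldl LDL cholesterol, mmol/L.
#' @param apob apolipoprotein B, g/L (optional, NA allowed).
#' @param apoa1 apolipoprotein A-I, g/L (optional, NA allowed).
#' @return Data frame with columns `non_hdl`, `ai`, `aip`, `lci`,
#'   `ldl_hdl`, `apob_apoa1`.
#' @export
compute_indices <- function(tc, tg, hdl, ldl, apob = NA_real_,
                            apoa1 = NA_real_) {
  n <- length(tc)
  stopifnot(length(tg) == n, length(hdl) == n, length(ldl) == n)
  if (any(!is.finite(hdl) | hdl <= 0)) stop("hdl must be > 0")
  if (any(!is.finite(tg) | tg <= 0)) stop("tg must be > 0")
  if (any(!is.finite(tc) | tc <= 0)) stop("tc must be > 0")
  if (any(!is.finite(ldl) | ldl <= 0)) stop("ldl must be > 0")
  apob <- rep_len(as.numeric(apob), n)
  apoa1 <- rep_len(as.numeric(apoa1), n)

  non_hdl <- tc - hdl
  if (any(non_hdl < 0)) {
    warning(sum(non_hdl < 0),
            " panel(s) with tc < hdl: negative non-HDL-C returned")
  }
  data.frame(
    non_hdl = non_hdl,
    ai = non_hdl / hdl,
    aip = log10(tg / hdl),
    lci = tc * tg * ldl / hdl,
    ldl_hdl = ldl / hdl,
    apob_apoa1 = ifelse(!is.na(apob) & !is.na(apoa1) & apoa1 > 0,
                        apob / apoa1, NA_real_)
  )
}

# canonical analysis parameter set: LDL-C referent plus the competitors
lipid_parameters <- function() {
  c("ldl_c", "non_hdl", "ai", "aip", "lci", "ldl_hdl", "apob_apoa1", "lpa")
}
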