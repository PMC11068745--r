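#' Foxp3 TSDR demethylation percentage from qPCR Ct values
#'
#' Computes the demethylation percentage of the Treg-specific demethylated
#' region from the Ct values of the methylation-specific and
#' demethylation-specific reactions:
#'
#'   `100 / (1 + 2^(Ct_meth - Ct_demeth))`
#'
#' The default (`"as_printed"`) uses this exponent sign as is. Note its
#' consequence: a fully demethylated template amplifies earlier in the
#' demethylation-specific reaction (Ct_demeth < Ct_meth), making the
#' exponent positive is required for a value near 100 — i.e. under
#' `"as_printed"` large demethylation corresponds to Ct_meth >> Ct_demeth.
#' `"flipped"` uses `100 / (1 + 2^(Ct_demeth - Ct_meth))` for labs using
#' the opposite subtraction order. The convention is recorded in the
#' result's `convention` attribute.
#'
#' @param ct_meth Ct of the methylation-specific reaction (cycles).
#' @param ct_demeth Ct of the demethylation-specific reaction (cycles).
#' @param convention `"as_printed"` or `"flipped"`.
#' @return Demethylation percentage, strictly in (0, 100); NA (with a
#'   warning) where either Ct is missing. Vectorised.
#' @export
demethylation_percent <- function(ct_meth, ct_demeth,
                                  convention = c("as_printed", "flipped")) {
  convention <- match.arg(convention)
  if (any(is.infinite(ct_meth), is.infinite(ct_demeth)))
    stop("Ct values must be finite")
  miss <- is.na(ct_meth) | is.na(ct_demeth)
  if (any(miss)) warning(sum(miss), " sample(s) with missing Ct -> NA")
  dct <- ct_meth - ct_demeth
  if (convention == "flipped") dct <- -dct
  out <- 100 / (1 + 2^dct)
  out[miss] <- NA_real_
  structure(out, convention = convention)
}

#' Batch TSDR computation over a Ct table
#'
#' Applies [demethylation_percent()] row-wise to a table (or CSV file)
#' with columns `sample_id`, `ct_meth`, `ct_demeth`. Malformed rows
#' (blank or non-numeric Ct) yield NA with a warning naming the row;
#' processing continues. If a `group` column is present, per-group mean
#' and SD are attached as attribute `group_summary`.
#'
#' @param samples data frame or path to a CSV file.
#' @param convention see [demethylation_percent()].
#' @return The input table with a `demethylation_percent` column.
#' @export
batch_tsdr <- function(samples, convention = c("as_printed", "flipped")) {
  convention <- match.arg(convention)
  if (is.character(samples)) samples <- utils::read.csv(samples)
  needed <- c("sample_id", "ct_meth", "ct_demeth")
  if (!all(needed %in% names(samples)))
    stop("table must have columns: ", paste(needed, collapse = ", "))
  cm <- suppressWarnings(as.numeric(samples$ct_meth))
  cd <- suppressWarnings(as.numeric(samples$ct_demeth))
  bad <- which(is.na(cm) | is.na(cd))
  for (r in bad)
    warning("row ", r, " (", samples$sample_id[r],
            "): unusable Ct values -> NA", call. = FALSE)
  pct <- rep(NA_real_, nrow(samples))
  ok <- setdiff(seq_len(nrow(samples)), bad)
  if (length(ok))
    pct[ok] <- as.numeric(demethylation_percent(cm[ok], cd[ok], convention))
  samples$demethylation_percent <- pct
  if ("group" %in% names(samples)) {
    gs <- do.call(rbind, lapply(split(samples, samples$group), function(g)
      data.frame(group = g$group[1],
                 mean = mean(g$demethylation_percent, na.rm = TRUE),
                 sd = stats::sd(g$demethylation_percent, na.rm = TRUE),
                 n = sum(!is.na(g$demethylation_percent)))))
    rownames(gs) <- NULL
    attr(samples, "group_summary") <- gs
  }
  attr(samples, "convention") <- convention
  samples
}

#' Generate synthetic Ct pairs for a known demethylation fraction
#'
#' Inverts the demethylation formula: for a true fraction `f` (percent),
#' the noiseless Ct difference is `delta = log2(100/f - 1)`; Ct pairs are
#' drawn as `ct_demeth = ct_base + e1`, `ct_meth = ct_base + delta + e2`
#' with independent Gaussian Ct noise. At zero noise the formula recovers
#' `f` exactly.
#'
#' @param true_fraction true demethylation percent, strictly in (0, 100).
#' @param ct_base baseline Ct (cycles).
#' @param noise_sd Gaussian Ct noise SD (cycles), >= 0.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @return Data frame `sample_id`, `ct_meth`, `ct_demeth` with attribute
#'   `true_fraction`.
#' @export
synth_tsdr <- function(true_fraction, ct_base = 25, noise_sd = 0,
                       n = 1, seed = 1L) {
  if (!is.finite(true_fraction) || true_fraction <= 0 ||
      true_fraction >= 100)
    stop("true_fraction must lie strictly between 0 and 100 (the Ct difference is infinite at the boundaries)")
  stopifnot(noise_sd >= 0, n >= 1)
  set.seed(seed)
  delta <- log2(100 / true_fraction - 1)
  ct_demeth <- ct_base + stats::rnorm(n, 0, noise_sd)
  ct_meth <- ct_base + delta + stats::rnorm(n, 0, noise_sd)
  structure(data.frame(sample_id = sprintf("synth_%03d", seq_len(n)),
                       ct_meth = ct_meth, ct_demeth = ct_demeth),
            true_fraction = true_fraction)
}
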