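#' Spike-in-normalized relative RNA levels from RT-qPCR Ct values
#'
#' Relative RNA quantification against a spike-in of cells from another
#' species: technical replicates are averaged first, then per biological
#' replicate the target level is `efficiency^-(Ct_target - Ct_spike)`,
#' and levels are expressed relative to the same quantity in the reference
#' sample (untreated/pre-treatment), which is therefore exactly 1. Because
#' the spike Ct enters as a difference, any global additive Ct shift (e.g.
#' loading or recovery differences) cancels exactly. Mean and sample SD are
#' taken over biological replicates after normalization.
#'
#' @param measurements Long-format tibble with columns `target`, `sample`,
#'   `role` (`"target"` or `"spike"`), `bio_replicate`, `tech_replicate`,
#'   `ct` (cycles, > 0).
#' @param reference_sample Sample label serving as the unit reference.
#' @param efficiency Amplification efficiency per cycle (default 2, perfect
#'   doubling).
#' @return Tibble: `target`, `sample`, `mean_level`, `sd_level`, `n`.
#' @export
spike_normalized_rna <- function(measurements, reference_sample,
                                 efficiency = 2) {
  stopifnot(all(measurements$ct > 0))
  x <- dplyr::summarise(
    dplyr::group_by(measurements, .data$target, .data$sample, .data$role,
                    .data$bio_replicate),
    ct = mean(.data$ct), .groups = "drop")
  tg <- x[x$role == "target", ]
  sp <- x[x$role == "spike", ]
  spike_ct <- sp$ct[match(paste(tg$sample, tg$bio_replicate),
                          paste(sp$sample, sp$bio_replicate))]
  drop <- is.na(spike_ct)
  if (any(drop)) {
    warning("sample(s) without spike Ct dropped: ",
            paste(unique(tg$sample[drop]), collapse = ", "))
    tg <- tg[!drop, ]
    spike_ct <- spike_ct[!drop]
  }
  tg$level <- efficiency^-(tg$ct - spike_ct)
  ref <- tg[tg$sample == reference_sample, ]
  ref_level <- ref$level[match(paste(tg$target, tg$bio_replicate),
                               paste(ref$target, ref$bio_replicate))]
  tg$rel <- tg$level / ref_level
  dplyr::summarise(
    dplyr::group_by(tg, .data$target, .data$sample),
    mean_level = mean(.data$rel),
    sd_level = if (dplyr::n() >= 2L) stats::sd(.data$rel) else NA_real_,
    n = dplyr::n(),
    .groups = "drop")
}

#' ChIP-qPCR enrichment as percent of input
#'
#' Per locus and sample, `percent_input = 100 * input_dilution_factor *
#' efficiency^(Ct_input - Ct_ip)`, averaged (mean, sample SD) over
#' biological replicates after technical replicates are averaged. Loci with
#' an unpaired IP or input Ct in a replicate are dropped with a warning.
#'
#' @param measurements Long-format tibble with columns `target` (locus),
#'   `sample`, `role` (`"ip"` or `"input"`), `bio_replicate`,
#'   `tech_replicate`, `ct`.
#' @param input_dilution_factor Input dilution correction (e.g. 1 if the
#'   input Ct is already adjusted; default 1).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Tibble: `target`, `sample`, `mean_percent_input`,
#'   `sd_percent_input`, `n`.
#' @export
chip_qpcr_enrichment <- function(measurements, input_dilution_factor = 1,
                                 efficiency = 2) {
  stopifnot(all(measurements$ct > 0))
  x <- dplyr::summarise(
    dplyr::group_by(measurements, .data$target, .data$sample, .data$role,
                    .data$bio_replicate),
    ct = mean(.data$ct), .groups = "drop")
  ip <- x[x$role == "ip", ]
  inp <- x[x$role == "input", ]
  key <- function(d) paste(d$target, d$sample, d$bio_replicate)
  in_ct <- inp$ct[match(key(ip), key(inp))]
  drop <- is.na(in_ct)
  if (any(drop)) {
    warning("unpaired locus/replicate dropped: ",
            paste(unique(paste(ip$target[drop], ip$sample[drop])),
                  collapse = ", "))
    ip <- ip[!drop, ]
    in_ct <- in_ct[!drop]
  }
  ip$percent_input <- 100 * input_dilution_factor *
    efficiency^(in_ct - ip$ct)
  dplyr::summarise(
    dplyr::group_by(ip, .data$target, .data$sample),
    mean_percent_input = mean(.data$percent_input),
    sd_percent_input = if (dplyr::n() >= 2L)
      stats::sd(.data$percent_input) else NA_real_,
    n = dplyr::n(),
    .groups = "drop")
}
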