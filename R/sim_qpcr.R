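#' Simulate multiplexed qPCR Ct measurements for known sdY copy numbers
#'
#' Generates cycle-threshold records for the three-target multiplex assay
#' (reference gene `gapdh` plus the two sdY amplicons). The reference gene
#' amplifies at `ct_reference_mean`; a sample with `c >= 1` total sdY copies
#' yields sdY amplicon Ct values of `ct_reference_mean - log2(c)` (perfect
#' doubling efficiency, one cycle per doubling), so the downstream
#' 2^-ddCt fold change against a one-copy calibrator equals `c` exactly when
#' noise is zero. Gaussian noise of sd `ct_noise_sd` is added independently
#' to every replicate of every target. Zero-copy samples never amplify the
#' sdY targets; any simulated Ct above `dropout_ct_cutoff` is censored to
#' "no amplification" (`NA`).
#'
#' @param true_copies Integer vector in 0..3, total sdY copies per sample.
#' @param sample_ids Sample identifiers (defaults to `s1`, `s2`, ...).
#' @param config An [sdy_sim_config()] supplying the noise model parameters.
#' @return Tibble with columns `sample`, `target`, `replicate`, `ct`
#'   (`NA` = no amplification).
#' @examples
#' cfg <- sdy_sim_config(ct_noise_sd = 0)
#' simulate_qpcr(0:3, config = cfg)
#' @export
simulate_qpcr <- function(true_copies,
                          sample_ids = paste0("s", seq_along(true_copies)),
                          config = sdy_sim_config()) {
  stopifnot(all(true_copies %in% 0:3), length(sample_ids) == length(true_copies),
            !anyDuplicated(sample_ids))
  grid <- crossing(
    tibble(sample = sample_ids, copies = as.integer(true_copies)),
    target = .sdy_targets,
    replicate = seq_len(config$n_replicates)
  )
  mu <- ifelse(
    grid$target == "gapdh",
    config$ct_reference_mean,
    ifelse(grid$copies == 0, NA_real_,
           config$ct_reference_mean - log2(pmax(grid$copies, 1)))
  )
  ct <- mu + rnorm(nrow(grid), 0, config$ct_noise_sd)
  ct[!is.na(ct) & ct > config$dropout_ct_cutoff] <- NA_real_
  grid %>%
    mutate(ct = ct) %>%
    select("sample", "target", "replicate", "ct") %>%
    arrange(match(.data$sample, sample_ids), match(.data$target, .sdy_targets),
            .data$replicate)
}
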