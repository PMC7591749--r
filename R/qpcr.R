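#' Aggregate replicate Ct measurements
#'
#' Collapses replicate wells to one Ct per (sample, target). All-numeric
#' replicates are averaged; a target whose replicates all failed to amplify
#' is reported `absent`; a mix of amplifying and non-amplifying replicates is
#' flagged `failed` (default policy: partial dropout is treated as a
#' technical failure, never silently averaged), as is an all-numeric set
#' whose range exceeds `max_spread` cycles.
#'
#' @param ct Tibble with columns `sample`, `target`, `replicate`, `ct`
#'   (`NA` = no amplification).
#' @param max_spread Maximum allowed range (cycles) among numeric replicates.
#' @return Tibble with one row per (sample, target): `ct_mean`, `n_rep`,
#'   `status` in `ok` / `absent` / `failed`.
#' @export
aggregate_replicates <- function(ct, max_spread = 1) {
  stopifnot(all(c("sample", "target", "replicate", "ct") %in% names(ct)))
  dup <- ct %>% count(.data$sample, .data$target, .data$replicate) %>% filter(n > 1)
  if (nrow(dup)) abort("replicate indices must be unique per (sample, target)")
  ct %>%
    group_by(.data$sample, .data$target) %>%
    summarise(
      n_rep = n(),
      n_num = sum(!is.na(.data$ct)),
      spread = if (sum(!is.na(.data$ct)) > 1) diff(range(.data$ct, na.rm = TRUE)) else 0,
      ct_mean = if (sum(!is.na(.data$ct)) > 0) mean(.data$ct, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(
      status = case_when(
        .data$n_num == 0 ~ "absent",
        .data$n_num < .data$n_rep ~ "failed",
        .data$spread > max_spread ~ "failed",
        TRUE ~ "ok"
      ),
      ct_mean = ifelse(.data$status == "ok", .data$ct_mean, NA_real_)
    ) %>%
    select("sample", "target", "ct_mean", "n_rep", "status")
}

#' Compute 2^-ddCt fold changes against a one-copy calibrator
#'
#' Implements the comparative-Ct (Livak) method for the multiplex sdY assay.
#' For each run the calibrator delta-Ct of an sdY amplicon is the mean of
#' `Ct_target - Ct_reference` over the designated reference (one-copy XY)
#' males of that run; a sample's fold change is then
#' `FC = 2^-[(Ct_target,sample - Ct_ref,sample) - dCt_calibrator]`. An sdY
#' amplicon that did not amplify has an absent fold change; a sample whose
#' reference gene is absent or failed is flagged and gets no fold changes.
#'
#' @param ct_agg Aggregated Ct table from [aggregate_replicates()].
#' @param samples Tibble (`sample`, `run`, `is_reference_male`) giving run
#'   membership and the calibrator panel.
#' @param reference_target Reference gene target name.
#' @param targets The sdY amplicon target names (exon 2 and exon 4).
#' @return Tibble with one row per sample: `run`, `reference_status`,
#'   and per amplicon `fc_ex2` / `fc_ex4` with `status_ex2` / `status_ex4`
#'   in `ok` / `absent` / `failed`.
#' @export
compute_fold_change <- function(ct_agg, samples,
                                reference_target = "gapdh",
                                targets = c("sdy_ex2", "sdy_ex4")) {
  stopifnot(length(targets) == 2,
            all(c("sample", "run", "is_reference_male") %in% names(samples)))
  dat <- ct_agg %>%
    inner_join(samples, by = "sample") %>%
    filter(.data$target %in% c(reference_target, targets))

  ref <- dat %>%
    filter(.data$target == reference_target) %>%
    select("sample", "run", ref_ct = "ct_mean", ref_status = "status")
  missing_ref <- setdiff(unique(samples$sample), ref$sample)
  if (length(missing_ref)) {
    ref <- bind_rows(ref, tibble(
      sample = missing_ref,
      run = samples$run[match(missing_ref, samples$sample)],
      ref_ct = NA_real_, ref_status = "failed"
    ))
  }

  dct <- dat %>%
    filter(.data$target %in% targets) %>%
    left_join(select(ref, "sample", "ref_ct", "ref_status"), by = "sample") %>%
    mutate(dct = .data$ct_mean - .data$ref_ct)

  cal <- dct %>%
    filter(.data$is_reference_male, .data$status == "ok",
           .data$ref_status == "ok") %>%
    group_by(.data$run, .data$target) %>%
    summarise(cal_dct = mean(.data$dct), .groups = "drop")
  runs_needed <- crossing(run = unique(samples$run), target = targets)
  missing_cal <- anti_join(runs_needed, cal, by = c("run", "target"))
  if (nrow(missing_cal)) {
    abort(sprintf("no valid reference-male calibrator for run(s): %s",
                  paste(unique(missing_cal$run), collapse = ", ")))
  }

  suffix <- c("ex2", "ex4")
  wide <- dct %>%
    left_join(cal, by = c("run", "target")) %>%
    mutate(
      fc = ifelse(.data$status == "ok" & .data$ref_status == "ok",
                  2^(-(.data$dct - .data$cal_dct)), NA_real_),
      amp = suffix[match(.data$target, targets)]
    ) %>%
    select("sample", "run", "ref_status", "amp", "fc", "status") %>%
    pivot_wider(names_from = "amp", values_from = c("fc", "status"),
                names_sep = "_")
  wide %>%
    mutate(reference_status = .data$ref_status) %>%
    select("sample", "run", "reference_status",
           "fc_ex2", "fc_ex4", "status_ex2", "status_ex4") %>%
    arrange(match(.data$sample, unique(samples$sample)))
}

#' Fold-change band edges for copy-number calling
#'
#' The assay-validation rule places the one-copy/two-copy decision boundary
#' at fold change 1.5 on both sdY amplicons; the remaining edges extend that
#' rule symmetrically on the linear scale: 2.5 separates two from three
#' copies, 0.5 guards against partial-degradation artefacts below the
#' one-copy cluster, and 3.5 caps the three-copy band.
#'
#' @param lower_min,one_two,two_three,upper_max Band edges (fold change).
#' @return Named list of band edges.
#' @export
sdy_bands <- function(lower_min = 0.5, one_two = 1.5, two_three = 2.5,
                      upper_max = 3.5) {
  stopifnot(lower_min < one_two, one_two < two_three, two_three < upper_max)
  list(lower_min = lower_min, one_two = one_two, two_three = two_three,
       upper_max = upper_max)
}

.fc_band <- function(fc, status, bands) {
  case_when(
    status == "absent" ~ 0L,
    status != "ok" | is.na(fc) ~ NA_integer_,
    fc > bands$lower_min & fc <= bands$one_two ~ 1L,
    fc > bands$one_two & fc <= bands$two_three ~ 2L,
    fc > bands$two_three & fc <= bands$upper_max ~ 3L,
    TRUE ~ NA_integer_
  )
}

#' Call integer sdY copy number from per-amplicon fold changes
#'
#' Each sdY amplicon is banded independently (absent -> 0; (0.5, 1.5] -> 1;
#' (1.5, 2.5] -> 2; (2.5, 3.5] -> 3 by default). A definite call requires
#' the two amplicon bands to agree; disagreeing, out-of-range or
#' single-amplicon-dropout patterns are reported `ambiguous`, never
#' averaged. A zero-copy call additionally requires a valid reference gene,
#' and a failed reference makes the whole sample `failed`.
#'
#' @param fc Fold-change table from [compute_fold_change()].
#' @param bands Band edges from [sdy_bands()].
#' @return Tibble with one row per sample: `band_ex2`, `band_ex4`, `copies`
#'   (integer 0..3, `NA` unless status `ok`), `status` in
#'   `ok` / `ambiguous` / `failed`.
#' @export
call_copy_number <- function(fc, bands = sdy_bands()) {
  fc %>%
    mutate(
      band_ex2 = .fc_band(.data$fc_ex2, .data$status_ex2, bands),
      band_ex4 = .fc_band(.data$fc_ex4, .data$status_ex4, bands),
      status = case_when(
        .data$reference_status != "ok" ~ "failed",
        is.na(.data$band_ex2) | is.na(.data$band_ex4) ~ "ambiguous",
        .data$band_ex2 == .data$band_ex4 ~ "ok",
        TRUE ~ "ambiguous"
      ),
      copies = ifelse(.data$status == "ok", .data$band_ex2, NA_integer_)
    ) %>%
    select("sample", "band_ex2", "band_ex4", "copies", "status")
}
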