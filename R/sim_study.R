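#' Generate a complete synthetic study
#'
#' Simulates the full multi-family cross design: pedigree, true sdY
#' genotypes, SNP and microsatellite genotypes for parents and offspring, a
#' reference-male calibrator panel, and replicate qPCR Ct measurements for
#' every individual. All randomness flows from the single `seed`, so the
#' same seed reproduces the study exactly.
#'
#' @param config An [sdy_sim_config()].
#' @param seed Integer seed for the single random generator.
#' @return A list of class `sdy_study` with tibbles `pedigree`, `crosses`,
#'   `genotypes_snp`, `genotypes_msat`, `linkage_map`, `qpcr_ct`, `samples`
#'   (calibrator membership), `truth`, plus the `config` and `seed` used.
#' @seealso [write_study()], [read_study()], [run_pipeline()]
#' @export
generate_study <- function(config = sdy_sim_config(), seed = 1) {
  withr::local_seed(seed)
  carriers <- config$carriers
  fams <- map(seq_len(config$n_families), function(i) {
    fid <- config$family_ids[i]
    row <- carriers[carriers$family == fid, ]
    simulate_family(
      sire_auto = if (nrow(row)) row$sire_auto[1] else 0L,
      dam_auto = if (nrow(row)) row$dam_auto[1] else 0L,
      config = config, family_id = fid
    )
  })
  pedigree <- map_dfr(fams, "pedigree")
  truth <- map_dfr(fams, "truth")
  genotypes_snp <- map_dfr(fams, "genotypes_snp")
  genotypes_msat <- map_dfr(fams, "genotypes_msat")
  crosses <- pedigree %>%
    filter(.data$generation == "P") %>%
    group_by(.data$family) %>%
    summarise(sire = .data$id[.data$phenotypic_sex == "M"],
              dam = .data$id[.data$phenotypic_sex == "F"], .groups = "drop")

  ref_ids <- sprintf("REF%02d", seq_len(config$n_reference_males))
  truth <- bind_rows(
    truth,
    tibble(id = ref_ids, y_copies = 1L, auto_copies = 0L, family = NA_character_)
  )
  qpcr_ct <- simulate_qpcr(
    true_copies = truth$y_copies + pmin(truth$auto_copies, 3L - truth$y_copies),
    sample_ids = truth$id, config = config
  )
  samples <- tibble(
    sample = truth$id, run = "run1",
    is_reference_male = truth$id %in% ref_ids
  )
  structure(
    list(
      pedigree = pedigree, crosses = crosses,
      genotypes_snp = genotypes_snp, genotypes_msat = genotypes_msat,
      linkage_map = config$map, qpcr_ct = qpcr_ct, samples = samples,
      truth = truth, config = config, seed = seed
    ),
    class = "sdy_study"
  )
}

#' @export
print.sdy_study <- function(x, ...) {
  n_off <- sum(x$pedigree$generation == "F1")
  cat(sprintf("<sdy_study> seed %s: %d families, %d offspring, %d SNPs, %d qPCR rows\n",
              x$seed, nrow(x$crosses), n_off, nrow(x$linkage_map),
              nrow(x$qpcr_ct)))
  invisible(x)
}

.tsv_files <- c(
  pedigree = "pedigree.tsv", crosses = "crosses.tsv",
  genotypes_snp = "genotypes_snp.tsv", genotypes_msat = "genotypes_msat.tsv",
  linkage_map = "linkage_map.tsv", qpcr_ct = "qpcr_ct.tsv",
  samples = "samples.tsv", truth = "truth.tsv"
)

#' Write a study to a directory of TSV files
#'
#' One TSV per table, each with a commented header recording the package
#' version and simulation seed. Missing genotype alleles are written as "."
#' and non-amplifying qPCR reactions as "NA".
#'
#' @param study An `sdy_study` (or any named list of the same tables).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# sdyped %s%s",
                    as.character(utils::packageVersion("sdyped")),
                    if (!is.null(study$seed)) paste0(" seed=", study$seed) else "")
  for (nm in names(.tsv_files)) {
    tab <- study[[nm]]
    if (is.null(tab)) next
    if (nm %in% c("genotypes_snp", "genotypes_msat")) {
      tab <- mutate(tab, across(c("allele1", "allele2"),
                                ~ ifelse(is.na(.x), ".", .x)))
    }
    path <- file.path(dir, .tsv_files[[nm]])
    writeLines(header, path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE, na = "NA")
  }
  invisible(dir)
}

#' Read a study back from a directory of TSV files
#'
#' Reads whichever of the standard tables are present (commented `#` header
#' lines are skipped) and restores the missing-value conventions of
#' [write_study()].
#'
#' @param dir Directory holding the TSV files.
#' @return A list of class `sdy_study` (without `config`).
#' @export
read_study <- function(dir) {
  out <- list()
  for (nm in names(.tsv_files)) {
    path <- file.path(dir, .tsv_files[[nm]])
    if (!file.exists(path)) next
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    if (nm %in% c("genotypes_snp", "genotypes_msat")) {
      tab <- mutate(tab, across(c("allele1", "allele2"),
                                ~ ifelse(.x == ".", NA_character_, as.character(.x))))
    }
    out[[nm]] <- tab
  }
  if (!length(out)) abort(sprintf("no study tables found in %s", dir))
  structure(out, class = "sdy_study")
}
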