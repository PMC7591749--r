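#' Drop families below the minimum-size cohort filter
#'
#' Families represented by fewer than `min_family_size` assigned offspring
#' are discarded from the analysis cohort (the default of 10 matches the
#' usual maturity filter of pedigree-controlled designs).
#'
#' @param assignments Assignment table from [assign_parentage()].
#' @param min_family_size Minimum number of assigned offspring per family.
#' @param quiet Suppress the removal log message.
#' @return List with `assignments` (rows of retained, assigned offspring),
#'   `retained` (family sizes kept) and `removed` (family sizes dropped).
#' @export
filter_families <- function(assignments, min_family_size = 10, quiet = FALSE) {
  assigned <- filter(assignments, .data$status == "assigned")
  sizes <- count(assigned, .data$family, name = "n_offspring")
  removed <- filter(sizes, .data$n_offspring < min_family_size)
  retained <- filter(sizes, .data$n_offspring >= min_family_size)
  if (!quiet && nrow(removed)) {
    inform(sprintf("filter_families: removed %d famil%s below %d offspring (%s)",
                   nrow(removed), if (nrow(removed) == 1) "y" else "ies",
                   min_family_size,
                   paste(removed$family, collapse = ", ")))
  }
  list(
    assignments = semi_join(assigned, retained, by = "family"),
    retained = retained, removed = removed
  )
}

# Parental pseudocopy configuration for one family: parents' own qPCR calls
# when definite (sire pseudocopies = copies - 1 for an XY sire), otherwise
# maximum likelihood from the offspring counts.
.family_config <- function(fam, crosses, calls, offspring_counts) {
  cross <- crosses[crosses$family == fam, ]
  sire_call <- calls$copies[match(cross$sire, calls$sample)]
  dam_call <- calls$copies[match(cross$dam, calls$sample)]
  sire_auto <- if (length(sire_call) && !is.na(sire_call))
    max(sire_call - 1L, 0L) else NA_integer_
  dam_auto <- if (length(dam_call) && !is.na(dam_call))
    as.integer(dam_call) else NA_integer_
  source <- "parent_calls"
  if (is.na(sire_auto) || is.na(dam_auto)) {
    fit <- infer_parental_config(offspring_counts,
                                 sire_call = if (!is.na(sire_auto)) sire_auto,
                                 dam_call = if (!is.na(dam_auto)) dam_auto)
    source <- "offspring_ml"
    if (fit$status != "ok" || nrow(fit$best) == 0) {
      return(tibble(family = fam, sire_auto = NA_integer_,
                    dam_auto = NA_integer_, config_source = "no_information"))
    }
    sire_auto <- fit$best$sire_auto[1]
    dam_auto <- fit$best$dam_auto[1]
  }
  tibble(family = fam, sire_auto = as.integer(sire_auto),
         dam_auto = as.integer(dam_auto), config_source = source)
}

.family_gof <- function(fam, cfg, offspring, replicates, seed) {
  map_dfr(c("F", "M"), function(sx) {
    obs_tab <- offspring %>%
      filter(.data$family == fam, .data$phenotypic_sex == sx,
             !is.na(.data$copies))
    if (nrow(obs_tab) == 0) return(tibble())
    probs <- offspring_distribution(cfg$sire_auto, cfg$dam_auto) %>%
      filter(.data$sex == sx) %>%
      mutate(prob = .data$prob / sum(.data$prob))
    cats <- sort(union(probs$total_copies, unique(obs_tab$copies)))
    obs <- setNames(tabulate(match(obs_tab$copies, cats), length(cats)),
                    cats)
    exp_p <- setNames(probs$prob[match(cats, probs$total_copies)], cats)
    exp_p[is.na(exp_p)] <- 0
    g <- gof_test(obs, exp_p, replicates = replicates,
                  seed = (seed + match(sx, c("F", "M"))) %% .Machine$integer.max)
    tibble(family = fam, stratum = sx, n = g$n, statistic = g$statistic,
           p_mc = g$p_mc, impossible = g$impossible,
           sire_auto = cfg$sire_auto, dam_auto = cfg$dam_auto)
  })
}

#' Run the full analysis pipeline on a study
#'
#' Orchestrates the stages end to end: copy-number calling from the Ct
#' table, exclusion-based parentage assignment, the minimum-family-size
#' cohort filter, discordance classification, per-family Monte-Carlo
#' goodness-of-fit of offspring copy-number counts against the autosomal
#' inheritance model, and (optionally) per-family linkage scans of sex and
#' of the discordance phenotype.
#'
#' @param study An `sdy_study` list (from [generate_study()] or
#'   [read_study()]) or a directory path of study TSV files.
#' @param min_family_size Cohort filter (see [filter_families()]).
#' @param max_mismatch Parentage mismatch tolerance.
#' @param bands Fold-change band edges ([sdy_bands()]).
#' @param gof_replicates Monte-Carlo replicates per goodness-of-fit test.
#' @param seed Seed for the Monte-Carlo p-values.
#' @param run_scans Run the SNP linkage scans (the slowest stage).
#' @param out_dir Optional directory; when given, every stage output is
#'   written there as TSV.
#' @return A list of class `sdy_pipeline` with elements `calls`,
#'   `fold_changes`, `assignments`, `retained_families`, `discordance`,
#'   `parental_configs`, `families_gof`, `scan_sex`, `scan_discordance`,
#'   `scan_summary`, `scan_comparison` and `report`.
#' @export
run_pipeline <- function(study, min_family_size = 10, max_mismatch = 0,
                         bands = sdy_bands(), gof_replicates = 1e4,
                         seed = 1, run_scans = TRUE, out_dir = NULL) {
  if (is.character(study)) study <- read_study(study)
  needed <- c("pedigree", "crosses", "genotypes_msat", "qpcr_ct", "samples")
  missing <- setdiff(needed, names(study))
  if (length(missing)) {
    abort(sprintf("study is missing required tables: %s",
                  paste(missing, collapse = ", ")))
  }

  fc <- compute_fold_change(aggregate_replicates(study$qpcr_ct),
                            study$samples)
  calls <- call_copy_number(fc, bands = bands)

  assignments <- assign_parentage(study$genotypes_msat, study$crosses,
                                  max_mismatch = max_mismatch)
  flt <- filter_families(assignments, min_family_size = min_family_size,
                         quiet = TRUE)

  offspring <- flt$assignments %>%
    select(sample = "offspring_id", "family") %>%
    inner_join(select(study$pedigree, sample = "id", "phenotypic_sex"),
               by = "sample") %>%
    left_join(select(calls, "sample", "copies", "status"), by = "sample")

  discordance <- classify_discordance(
    select(offspring, "sample", "copies", "status"),
    select(study$pedigree, "id", "phenotypic_sex", "family")
  )

  fams <- sort(flt$retained$family)
  configs <- map_dfr(fams, function(fam) {
    .family_config(fam, study$crosses, calls,
                   offspring %>% filter(.data$family == fam) %>%
                     select(sex = "phenotypic_sex", "copies"))
  })
  gof <- map_dfr(seq_along(fams), function(i) {
    cfg <- configs[configs$family == fams[i], ]
    if (is.na(cfg$sire_auto)) return(tibble())
    .family_gof(fams[i], cfg, offspring, gof_replicates, seed + 2L * i)
  })

  scan_sex <- scan_discordance <- scan_summary <- scan_comparison <- NULL
  if (run_scans && !is.null(study$genotypes_snp) &&
      !is.null(study$linkage_map)) {
    ped_cohort <- flt$assignments %>%
      select(id = "offspring_id", "family") %>%
      left_join(study$crosses, by = "family") %>%
      inner_join(select(study$pedigree, "id", "phenotypic_sex"), by = "id")
    tr <- infer_transmission(study$genotypes_snp, ped_cohort,
                             map = study$linkage_map)
    scan_sex <- scan_trait(
      tr, phenotype = select(ped_cohort, "id", class = "phenotypic_sex"),
      genotypes = study$genotypes_snp, map = study$linkage_map, trait = "sex"
    )
    disc_pheno <- discordance %>%
      filter(.data$class != "unknown") %>%
      mutate(class = ifelse(.data$class == "concordant", "non_discrepant",
                            "discrepant")) %>%
      select(id = "sample", "class", "family")
    affected <- unique(disc_pheno$family[disc_pheno$class == "discrepant"])
    disc_pheno <- filter(disc_pheno, .data$family %in% affected)
    if (nrow(disc_pheno) && length(unique(disc_pheno$class)) == 2) {
      scan_discordance <- scan_trait(
        tr, phenotype = select(disc_pheno, "id", "class"),
        genotypes = study$genotypes_snp, map = study$linkage_map,
        trait = "discordance"
      )
    }
    scan_summary <- summarize_scan(bind_rows(scan_sex, scan_discordance))
    if (!is.null(scan_discordance)) {
      both <- scan_summary %>%
        filter(.data$family %in% affected)
      if (length(unique(both$trait)) == 2) {
        scan_comparison <- compare_scan_traits(both)
      }
    }
  }

  disc_off <- filter(discordance, .data$sample %in% offspring$sample)
  affected_families <- disc_off %>%
    filter(.data$class %in% c("discordant_female", "carrier_male")) %>%
    pull(.data$family) %>% unique() %>% sort()
  carrier_parent_families <- study$crosses %>%
    mutate(
      sire_copies = calls$copies[match(.data$sire, calls$sample)],
      dam_copies = calls$copies[match(.data$dam, calls$sample)],
      carrier = (!is.na(.data$sire_copies) & .data$sire_copies >= 2) |
        (!is.na(.data$dam_copies) & .data$dam_copies >= 1)
    ) %>%
    filter(.data$carrier, .data$family %in% fams) %>%
    pull(.data$family) %>% sort()

  report <- list(
    n_samples = length(unique(study$qpcr_ct$sample)),
    n_offspring_assigned = nrow(flt$assignments),
    assignment_rate = mean(assignments$status == "assigned"),
    n_families_retained = length(fams),
    families_removed = flt$removed,
    n_discordant_females = sum(disc_off$class == "discordant_female"),
    n_carrier_males = sum(disc_off$class == "carrier_male"),
    affected_families = affected_families,
    carrier_parent_families = carrier_parent_families,
    gof_p_range = if (nrow(gof)) range(gof$p_mc, na.rm = TRUE) else NULL,
    seed = seed
  )

  out <- structure(
    list(calls = calls, fold_changes = fc, assignments = assignments,
         retained_families = flt$retained, discordance = discordance,
         parental_configs = configs, families_gof = gof,
         scan_sex = scan_sex, scan_discordance = scan_discordance,
         scan_summary = scan_summary, scan_comparison = scan_comparison,
         report = report),
    class = "sdy_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tabs <- c("calls", "fold_changes", "assignments", "discordance",
              "parental_configs", "families_gof", "scan_sex",
              "scan_discordance", "scan_summary", "scan_comparison")
    for (nm in tabs) {
      if (!is.null(out[[nm]]) && nrow(out[[nm]])) {
        readr::write_tsv(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
      }
    }
    writeLines(utils::capture.output(print(out)), file.path(out_dir, "report.txt"))
  }
  out
}

#' @export
print.sdy_pipeline <- function(x, ...) {
  r <- x$report
  cat("<sdy_pipeline report>\n")
  cat(sprintf("  samples genotyped:        %d\n", r$n_samples))
  cat(sprintf("  offspring assigned:       %d (rate %.3f)\n",
              r$n_offspring_assigned, r$assignment_rate))
  cat(sprintf("  families retained:        %d (removed: %d)\n",
              r$n_families_retained, nrow(r$families_removed)))
  cat(sprintf("  discordant females:       %d\n", r$n_discordant_females))
  cat(sprintf("  carrier males:            %d\n", r$n_carrier_males))
  cat(sprintf("  affected families:        %s\n",
              paste(r$affected_families, collapse = ", ")))
  cat(sprintf("  carrier-parent families:  %s\n",
              paste(r$carrier_parent_families, collapse = ", ")))
  if (!is.null(r$gof_p_range)) {
    cat(sprintf("  inheritance GoF p range:  %.3f - %.3f\n",
                r$gof_p_range[1], r$gof_p_range[2]))
  }
  if (!is.null(x$scan_comparison)) {
    cat(sprintf("  sex/discordance scans on same chromosome: %d of %d families\n",
                sum(x$scan_comparison$same_chromosome, na.rm = TRUE),
                nrow(x$scan_comparison)))
  }
  invisible(x)
}
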