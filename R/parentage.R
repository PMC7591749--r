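# Vectorised per-locus exclusion check. A locus is informative when all six
# alleles (offspring, sire, dam) are observed; it mismatches when neither
# assignment of the offspring's two alleles (one to each parent) is
# consistent with both parental genotypes.
.locus_compatible <- function(o1, o2, s1, s2, d1, d2) {
  informative <- !(is.na(o1) | is.na(o2) | is.na(s1) | is.na(s2) |
                     is.na(d1) | is.na(d2))
  ok1 <- (o1 == s1 | o1 == s2) & (o2 == d1 | o2 == d2)
  ok2 <- (o2 == s1 | o2 == s2) & (o1 == d1 | o1 == d2)
  list(informative = informative, compatible = informative & (ok1 | ok2))
}

#' Test one offspring against one candidate parental pair
#'
#' Exclusion-based trio check over a shared marker panel: at each locus the
#' offspring's two alleles must be assignable one to each parent such that
#' each assigned allele occurs in that parent's genotype. Loci with any
#' missing allele are skipped.
#'
#' @param offspring,sire,dam Genotype tibbles (`marker`, `allele1`,
#'   `allele2`) for the three individuals; `NA` = missing.
#' @param max_mismatch Number of mismatching loci tolerated (0 = strict
#'   exclusion).
#' @return A list: `verdict` (`compatible`, `incompatible` or
#'   `no_information`), `mismatches`, `n_informative`.
#' @examples
#' off <- tibble::tibble(marker = "m1", allele1 = "A", allele2 = "B")
#' sire <- tibble::tibble(marker = "m1", allele1 = "A", allele2 = "C")
#' dam <- tibble::tibble(marker = "m1", allele1 = "B", allele2 = "D")
#' pair_compatible(off, sire, dam)
#' @export
pair_compatible <- function(offspring, sire, dam, max_mismatch = 0) {
  trio <- offspring %>%
    inner_join(sire, by = "marker", suffix = c("", "_s")) %>%
    inner_join(dam, by = "marker", suffix = c("", "_d"))
  chk <- .locus_compatible(trio$allele1, trio$allele2,
                           trio$allele1_s, trio$allele2_s,
                           trio$allele1_d, trio$allele2_d)
  n_inf <- sum(chk$informative)
  mm <- sum(chk$informative & !chk$compatible)
  verdict <- if (n_inf == 0) "no_information"
    else if (mm <= max_mismatch) "compatible" else "incompatible"
  list(verdict = verdict, mismatches = mm, n_informative = n_inf)
}

#' Assign offspring to families by exclusion over all candidate pairs
#'
#' Every offspring is tested against every realised cross. An offspring is
#' assigned when exactly one pair is compatible at the mismatch tolerance;
#' zero compatible pairs give `unassigned`, several give `ambiguous`. When
#' `max_mismatch > 0`, ties among compatible pairs are first broken by
#' mismatch count; equal-mismatch ties remain ambiguous (no likelihood
#' ranking is attempted).
#'
#' @param genotypes Long genotype tibble (`id`, `marker`, `allele1`,
#'   `allele2`) covering offspring and all candidate parents.
#' @param crosses Tibble (`family`, `sire`, `dam`) of realised crosses.
#' @param offspring_ids Ids to assign; defaults to every genotyped id that
#'   is not a candidate parent.
#' @param max_mismatch Mismatch tolerance per pair (default 0).
#' @return Tibble with one row per offspring: `family` (`NA` unless
#'   assigned), `status` (`assigned` / `unassigned` / `ambiguous` /
#'   `no_information`), `n_compatible`, `best_mismatches`.
#' @export
assign_parentage <- function(genotypes, crosses, offspring_ids = NULL,
                             max_mismatch = 0) {
  stopifnot(all(c("id", "marker", "allele1", "allele2") %in% names(genotypes)),
            all(c("family", "sire", "dam") %in% names(crosses)))
  if (anyDuplicated(genotypes[, c("id", "marker")])) {
    abort("duplicate (id, marker) rows in genotypes")
  }
  parents <- unique(c(crosses$sire, crosses$dam))
  if (is.null(offspring_ids)) {
    offspring_ids <- setdiff(unique(genotypes$id), parents)
  }

  off <- genotypes %>%
    filter(.data$id %in% offspring_ids) %>%
    select(offspring_id = "id", "marker", o1 = "allele1", o2 = "allele2")
  pg <- function(ids, p1, p2) {
    genotypes %>%
      filter(.data$id %in% ids) %>%
      select("id", "marker", !!p1 := "allele1", !!p2 := "allele2")
  }
  grid <- crossing(off, crosses) %>%
    left_join(pg(crosses$sire, "s1", "s2"),
              by = c(sire = "id", marker = "marker")) %>%
    left_join(pg(crosses$dam, "d1", "d2"),
              by = c(dam = "id", marker = "marker"))
  chk <- .locus_compatible(grid$o1, grid$o2, grid$s1, grid$s2,
                           grid$d1, grid$d2)
  per_pair <- grid %>%
    mutate(informative = chk$informative,
           mismatch = chk$informative & !chk$compatible) %>%
    group_by(.data$offspring_id, .data$family) %>%
    summarise(n_informative = sum(.data$informative),
              mismatches = sum(.data$mismatch), .groups = "drop") %>%
    mutate(compatible = .data$n_informative > 0 &
             .data$mismatches <= max_mismatch)

  per_pair %>%
    group_by(.data$offspring_id) %>%
    summarise(
      any_info = any(.data$n_informative > 0),
      n_compatible = sum(.data$compatible),
      best_mismatches = ifelse(any(.data$compatible),
                               min(.data$mismatches[.data$compatible]),
                               NA_integer_),
      n_best = sum(.data$compatible &
                     .data$mismatches == suppressWarnings(
                       min(.data$mismatches[.data$compatible]))),
      family = ifelse(
        sum(.data$compatible &
              .data$mismatches == suppressWarnings(
                min(.data$mismatches[.data$compatible]))) == 1,
        .data$family[.data$compatible][
          which.min(.data$mismatches[.data$compatible])],
        NA_character_),
      .groups = "drop"
    ) %>%
    mutate(
      status = case_when(
        !.data$any_info ~ "no_information",
        .data$n_compatible == 0 ~ "unassigned",
        .data$n_best == 1 ~ "assigned",
        TRUE ~ "ambiguous"
      ),
      family = ifelse(.data$status == "assigned", .data$family, NA_character_)
    ) %>%
    select(offspring_id = "offspring_id", "family", "status",
           "n_compatible", "best_mismatches")
}
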