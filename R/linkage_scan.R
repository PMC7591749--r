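#' Deduce transmitted parental alleles for every trio at every marker
#'
#' Single-marker transmission inference: an offspring's two alleles are
#' attributed one to each parent when exactly one such attribution is
#' consistent with both parental genotypes. Phase-ambiguous trios (both
#' attributions possible with different outcomes, e.g. all three individuals
#' A/B) are left unresolved; trios in which an offspring allele occurs in
#' neither parent are flagged as Mendelian inconsistencies and never enter
#' the scan.
#'
#' With `resolve_phase = TRUE` (the default) a second, linkage-informed pass
#' rescues phase-ambiguous trios marker by marker: within each family and
#' parent, the parent's heterozygous markers on a chromosome are phased
#' against each other by majority vote over offspring resolved at
#' consecutive marker pairs, and an unresolved transmission is imputed from
#' the offspring's nearest resolved marker on the same phased segment. This
#' emulates the pedigree-plus-genotype IBD estimators used for family-based
#' scans and recovers the offspring that single-marker deduction must
#' discard at fully heterozygous markers; when the two parents' imputations
#' conflict the trio stays unresolved. Mendelian inconsistencies are never
#' rescued. A single isolated marker has no flanking information, so
#' single-trio behaviour is unchanged.
#'
#' @param genotypes Long genotype tibble (`id`, `marker`, `allele1`,
#'   `allele2`) covering offspring and parents; `NA` = missing.
#' @param pedigree Tibble with `id`, `sire`, `dam` (and ideally `family`);
#'   rows with a recorded sire and dam are treated as offspring.
#' @param map Optional linkage map (`marker`, `chromosome`, `cM`); required
#'   for the phase-rescue pass.
#' @param resolve_phase Run the linkage-informed rescue pass (needs `map`).
#' @return Tibble with one row per (offspring, marker): `paternal_allele`,
#'   `maternal_allele` (NA unless resolved), `status` in
#'   `ok` / `unresolved` / `missing` / `mendelian_error`, and `resolved_by`
#'   (`single_marker` or `phase`).
#' @export
infer_transmission <- function(genotypes, pedigree, map = NULL,
                               resolve_phase = !is.null(map)) {
  stopifnot(all(c("id", "marker", "allele1", "allele2") %in% names(genotypes)),
            all(c("id", "sire", "dam") %in% names(pedigree)))
  if (resolve_phase && is.null(map)) {
    abort("resolve_phase = TRUE requires a linkage map")
  }
  off <- pedigree %>%
    filter(!is.na(.data$sire), !is.na(.data$dam)) %>%
    select("id", "sire", "dam", any_of("family"))
  gen <- function(ids, n1, n2) {
    genotypes %>%
      filter(.data$id %in% ids) %>%
      select("id", "marker", !!n1 := "allele1", !!n2 := "allele2")
  }
  tr <- genotypes %>%
    semi_join(off, by = "id") %>%
    select(offspring_id = "id", "marker", o1 = "allele1", o2 = "allele2") %>%
    left_join(off, by = c(offspring_id = "id")) %>%
    left_join(gen(off$sire, "s1", "s2"), by = c(sire = "id", marker = "marker")) %>%
    left_join(gen(off$dam, "d1", "d2"), by = c(dam = "id", marker = "marker"))

  miss <- with(tr, is.na(o1) | is.na(o2) | is.na(s1) | is.na(s2) |
                 is.na(d1) | is.na(d2))
  ok1 <- with(tr, (o1 == s1 | o1 == s2) & (o2 == d1 | o2 == d2))
  ok2 <- with(tr, (o2 == s1 | o2 == s2) & (o1 == d1 | o1 == d2))
  same <- tr$o1 == tr$o2
  status <- case_when(
    miss ~ "missing",
    !ok1 & !ok2 ~ "mendelian_error",
    ok1 & ok2 & !same ~ "unresolved",
    TRUE ~ "ok"
  )
  tr <- tr %>%
    mutate(
      status = status,
      resolved_by = ifelse(status == "ok", "single_marker", NA_character_),
      paternal_allele = case_when(
        status != "ok" ~ NA_character_,
        ok1 ~ .data$o1,
        TRUE ~ .data$o2
      ),
      maternal_allele = case_when(
        status != "ok" ~ NA_character_,
        ok1 ~ .data$o2,
        TRUE ~ .data$o1
      )
    )
  if (resolve_phase && any(tr$status == "unresolved")) {
    tr <- .resolve_phase(tr, map)
  }
  tr %>%
    select("offspring_id", any_of("family"), "sire", "dam", "marker",
           "paternal_allele", "maternal_allele", "status", "resolved_by")
}

# Linkage-informed rescue of phase-ambiguous trios. For one parent of one
# family and one chromosome:
#   F[i, k]  = TRUE when offspring i received the parent's allele1 at het
#              marker k (NA when not resolved for that parent);
#   phi[k]   = relative phase of marker k against the segment's first het
#              marker, estimated by majority vote over offspring resolved at
#              consecutive pairs (no shared offspring breaks the segment);
#   H[i, k]  = F[i, k] XOR phi[k], the transmitted haplotype label, constant
#              along a non-recombinant chromosome.
# An unresolved (i, k*) inherits H from offspring i's nearest resolved
# marker in the same segment, which converts back to a transmitted allele.
.impute_side <- function(F, phi, seg, cm) {
  k <- ncol(F)
  H <- sweep(F, 2, phi, FUN = xor)
  out <- matrix(NA, nrow(F), k)
  for (j in seq_len(k)) {
    need <- is.na(F[, j])
    if (!any(need)) next
    cand <- which(seg == seg[j] & seq_len(k) != j)
    if (!length(cand)) next
    ord <- cand[order(abs(cm[cand] - cm[j]))]
    h <- rep(NA, sum(need))
    for (c in ord) {
      fill <- is.na(h) & !is.na(H[need, c])
      h[fill] <- H[which(need)[fill], c]
      if (!anyNA(h)) break
    }
    out[need, j] <- xor(h, phi[j])
  }
  out  # TRUE = parent's allele1 transmitted, imputed only where F was NA
}

.phase_one <- function(F, cm) {
  k <- ncol(F)
  phi <- logical(k)
  seg <- integer(k)
  seg[1] <- 1L
  if (k > 1) {
    for (j in 2:k) {
      both <- !is.na(F[, j - 1]) & !is.na(F[, j])
      if (!any(both)) {
        seg[j] <- seg[j - 1] + 1L
        phi[j] <- FALSE
      } else {
        coupled <- sum(F[both, j - 1] == F[both, j]) >= sum(both) / 2
        seg[j] <- seg[j - 1]
        phi[j] <- xor(phi[j - 1], !coupled)
      }
    }
  }
  list(phi = phi, seg = seg)
}

.resolve_phase <- function(tr, map) {
  tr <- left_join(tr, select(map, "marker", "chromosome", "cM"), by = "marker")
  idx_unres <- which(tr$status == "unresolved" & !is.na(tr$chromosome))
  if (!length(idx_unres)) {
    return(select(tr, -"chromosome", -"cM"))
  }
  for (side in c("sire", "dam")) {
    allele_col <- if (side == "sire") "paternal_allele" else "maternal_allele"
    p1 <- if (side == "sire") tr$s1 else tr$d1
    p2 <- if (side == "sire") tr$s2 else tr$d2
    het <- !is.na(p1) & !is.na(p2) & p1 != p2
    dat <- tr[het, ]
    dat$first <- ifelse(is.na(dat[[allele_col]]), NA,
                        dat[[allele_col]] == (if (side == "sire") dat$s1 else dat$d1))
    imp_col <- paste0("imp_", side)
    tr[[imp_col]] <- NA_character_
    fam_key <- if (!is.null(dat[["family"]])) dat$family else dat[[side]]
    groups <- split(which(het), paste(fam_key, dat[[side]],
                                      dat$chromosome, sep = "\r"))
    for (rows in groups) {
      sub <- tr[rows, ]
      firsts <- dat$first[match(rows, which(het))]
      mk <- unique(sub$marker[order(sub$cM)])
      if (length(mk) < 2) next
      offs <- unique(sub$offspring_id)
      F <- matrix(NA, length(offs), length(mk), dimnames = list(offs, mk))
      F[cbind(match(sub$offspring_id, offs), match(sub$marker, mk))] <- firsts
      if (!anyNA(F)) next
      cm <- sub$cM[match(mk, sub$marker)]
      ph <- .phase_one(F, cm)
      imp <- .impute_side(F, ph$phi, ph$seg, cm)
      cells <- which(!is.na(imp), arr.ind = TRUE)
      if (!nrow(cells)) next
      hit <- match(paste(offs[cells[, 1]], mk[cells[, 2]], sep = "\r"),
                   paste(sub$offspring_id, sub$marker, sep = "\r"))
      pa1 <- if (side == "sire") sub$s1[hit] else sub$d1[hit]
      pa2 <- if (side == "sire") sub$s2[hit] else sub$d2[hit]
      tr[[imp_col]][rows[hit]] <- ifelse(imp[cells], pa1, pa2)
    }
  }
  unres <- tr$status == "unresolved"
  # at an unresolved trio the offspring is het for the two parental alleles,
  # so fixing one parent's transmission fixes the other's as the remaining
  # allele; conflicting sire- and dam-side imputations stay unresolved
  other_allele <- function(given) ifelse(given == tr$o1, tr$o2, tr$o1)
  pat <- tr$imp_sire
  mat_from_pat <- other_allele(pat)
  mat <- tr$imp_dam
  pat_from_mat <- other_allele(mat)
  use_sire <- unres & !is.na(pat) &
    (is.na(mat) | mat == mat_from_pat)
  use_dam <- unres & is.na(pat) & !is.na(mat)
  tr$paternal_allele[use_sire] <- pat[use_sire]
  tr$maternal_allele[use_sire] <- mat_from_pat[use_sire]
  tr$paternal_allele[use_dam] <- pat_from_mat[use_dam]
  tr$maternal_allele[use_dam] <- mat[use_dam]
  rescued <- use_sire | use_dam
  tr$status[rescued] <- "ok"
  tr$resolved_by[rescued] <- "phase"
  select(tr, -"chromosome", -"cM", -"imp_sire", -"imp_dam")
}

# 2x2 Pearson chi-squared without continuity correction, via the closed form
# X2 = n (ad - bc)^2 / (r1 r2 c1 c2); NA when any margin is empty.
.chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ifelse(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0, NA_real_,
         n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
}

#' Per-family chi-squared linkage scan of a binary trait
#'
#' For every family, marker and heterozygous parent, cross-tabulates the
#' binary phenotype against the allele transmitted by that parent and
#' computes the 2x2 Pearson chi-squared statistic (1 df, no continuity
#' correction) with its asymptotic p-value. Unresolved or Mendelian-error
#' transmissions are omitted; markers with fewer than two informative
#' offspring, a single phenotype class, or a monomorphic transmitted allele
#' are skipped with a reason.
#'
#' @param transmissions Output of [infer_transmission()].
#' @param phenotype Tibble (`id`, `class`) with exactly two class labels
#'   (e.g. `M`/`F`, or `discordant`/`non_discordant`).
#' @param genotypes Long genotype tibble used to determine parental
#'   heterozygosity.
#' @param map Linkage map (`marker`, `chromosome`, `cM`).
#' @param trait Label stored in the result (e.g. `"sex"`).
#' @return Tibble of class `sdy_scan`: one row per (family, marker, parent)
#'   with the 2x2 counts, `chi_sq`, `p_value`, `n_informative`, and a
#'   `reason` for skipped combinations (`chi_sq` NA).
#' @export
scan_trait <- function(transmissions, phenotype, genotypes, map,
                       trait = "trait") {
  stopifnot(all(c("id", "class") %in% names(phenotype)))
  classes <- sort(unique(as.character(phenotype$class[!is.na(phenotype$class)])))
  if (length(classes) != 2) {
    abort("phenotype must have exactly two classes")
  }
  long <- transmissions %>%
    filter(.data$status == "ok") %>%
    inner_join(select(phenotype, offspring_id = "id", "class"),
               by = "offspring_id") %>%
    filter(!is.na(.data$class)) %>%
    pivot_longer(c("paternal_allele", "maternal_allele"),
                 names_to = "side", values_to = "allele") %>%
    mutate(parent = ifelse(.data$side == "paternal_allele", "sire", "dam"),
           parent_id = ifelse(.data$parent == "sire", .data$sire, .data$dam))
  het <- genotypes %>%
    mutate(het = !is.na(.data$allele1) & !is.na(.data$allele2) &
             .data$allele1 != .data$allele2) %>%
    select(parent_id = "id", "marker", "het", p1 = "allele1")
  res <- long %>%
    inner_join(het, by = c("parent_id", "marker")) %>%
    filter(.data$het) %>%
    mutate(first_allele = .data$allele == .data$p1,
           is_class1 = .data$class == classes[1]) %>%
    group_by(across(any_of(c("family", "marker", "parent")))) %>%
    summarise(
      n11 = sum(.data$is_class1 & .data$first_allele),
      n12 = sum(.data$is_class1 & !.data$first_allele),
      n21 = sum(!.data$is_class1 & .data$first_allele),
      n22 = sum(!.data$is_class1 & !.data$first_allele),
      .groups = "drop"
    ) %>%
    mutate(
      n_informative = .data$n11 + .data$n12 + .data$n21 + .data$n22,
      chi_sq = .chisq_2x2(.data$n11, .data$n12, .data$n21, .data$n22),
      reason = case_when(
        .data$n_informative < 2 ~ "fewer than 2 informative offspring",
        (.data$n11 + .data$n12) == 0 | (.data$n21 + .data$n22) == 0 ~
          "single phenotype class",
        (.data$n11 + .data$n21) == 0 | (.data$n12 + .data$n22) == 0 ~
          "monomorphic transmission",
        TRUE ~ NA_character_
      ),
      chi_sq = ifelse(is.na(.data$reason), .data$chi_sq, NA_real_),
      p_value = pchisq(.data$chi_sq, df = 1, lower.tail = FALSE)
    ) %>%
    left_join(select(map, "marker", "chromosome", "cM"), by = "marker") %>%
    mutate(trait = trait) %>%
    select("trait", any_of("family"), "marker", "chromosome", "cM", "parent",
           "n11", "n12", "n21", "n22", "n_informative", "chi_sq", "p_value",
           "reason") %>%
    arrange(across(any_of(c("family", "chromosome", "cM", "parent"))))
  class(res) <- c("sdy_scan", class(res))
  res
}

#' Summarise a linkage scan: top chromosome per family
#'
#' Ranks markers by p-value within each family (and trait) and reports the
#' best marker and its chromosome. Families in which every marker was
#' skipped are reported unmappable. A Sidak-style per-family adjustment of
#' the top p-value over the number of markers tested is included.
#'
#' @param scan An `sdy_scan` tibble from [scan_trait()] (scans for several
#'   traits may be row-bound first).
#' @return One row per (trait, family): `top_marker`, `top_chromosome`,
#'   `parent`, `chi_sq`, `p_value`, `p_sidak`, `n_markers_tested`, and
#'   `mappable`.
#' @export
summarize_scan <- function(scan) {
  scan %>%
    group_by(across(any_of(c("trait", "family")))) %>%
    summarise(
      n_markers_tested = sum(!is.na(.data$chi_sq)),
      mappable = n_markers_tested > 0,
      idx = if (mappable) which.min(.data$p_value) else NA_integer_,
      top_marker = if (mappable) .data$marker[idx] else NA_character_,
      top_chromosome = if (mappable) .data$chromosome[idx] else NA_character_,
      parent = if (mappable) .data$parent[idx] else NA_character_,
      chi_sq = if (mappable) .data$chi_sq[idx] else NA_real_,
      p_value = if (mappable) .data$p_value[idx] else NA_real_,
      .groups = "drop"
    ) %>%
    select(-"idx") %>%
    mutate(p_sidak = 1 - (1 - .data$p_value)^.data$n_markers_tested)
}

#' Compare sex-trait and discordance-trait scan summaries
#'
#' Joins per-family scan summaries for two traits and flags families whose
#' top chromosomes coincide -- the situation where the pseudocopy locus lies
#' on the sex-determining chromosome and both scans converge on it.
#'
#' @param summary A [summarize_scan()] result containing exactly two traits.
#' @return One row per family with `chromosome_<trait>` columns and
#'   `same_chromosome`.
#' @export
compare_scan_traits <- function(summary) {
  traits <- unique(summary$trait)
  stopifnot(length(traits) == 2)
  wide <- summary %>%
    select("trait", "family", "top_chromosome") %>%
    pivot_wider(names_from = "trait", values_from = "top_chromosome",
                names_prefix = "chromosome_")
  wide$same_chromosome <- wide[[2]] == wide[[3]]
  wide
}
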