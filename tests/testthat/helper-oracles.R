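# Independent oracles used to cross-check the package implementations.
# These deliberately use brute-force enumeration, not the package's code
# paths.

# Enumerate all 2 x 2 (sex haplotype x pseudo gamete-pair) outcomes of a
# cross and tally (sex, total copies) probabilities.
oracle_offspring_distribution <- function(sire_auto, dam_auto, sire_y = 1) {
  sire_sex_gametes <- if (sire_y == 2) c(1L, 1L) else c(1L, 0L) # Y carried?
  sire_pseudo <- c(rep(1L, sire_auto), rep(0L, 2 - sire_auto))
  dam_pseudo <- c(rep(1L, dam_auto), rep(0L, 2 - dam_auto))
  out <- list()
  for (sy in sire_sex_gametes) for (sp in sire_pseudo) for (dp in dam_pseudo) {
    sex <- if (sy == 1) "M" else "F"
    total <- sp + dp + sy
    key <- paste(sex, total)
    out[[key]] <- (out[[key]] %||% 0) + 1
  }
  probs <- unlist(out) / (length(sire_sex_gametes) * 4)
  parts <- do.call(rbind, strsplit(names(probs), " "))
  tibble::tibble(sex = parts[, 1], total_copies = as.integer(parts[, 2]),
                 prob = unname(probs)) |>
    dplyr::arrange(sex, total_copies)
}

# Trio compatibility by explicit enumeration of the two allele-to-parent
# assignments at each locus.
oracle_pair_compatible <- function(off, sire, dam) {
  loci <- intersect(intersect(off$marker, sire$marker), dam$marker)
  n_inf <- 0L
  mm <- 0L
  for (m in loci) {
    o <- unlist(off[off$marker == m, c("allele1", "allele2")])
    s <- unlist(sire[sire$marker == m, c("allele1", "allele2")])
    d <- unlist(dam[dam$marker == m, c("allele1", "allele2")])
    if (anyNA(c(o, s, d))) next
    n_inf <- n_inf + 1L
    ok <- FALSE
    for (perm in list(o, rev(o))) {
      if (perm[1] %in% s && perm[2] %in% d) ok <- TRUE
    }
    if (!ok) mm <- mm + 1L
  }
  list(n_informative = n_inf, mismatches = mm)
}

# Pearson 2x2 chi-squared from expected counts under independence (the
# package uses the n(ad-bc)^2 closed form instead).
oracle_chisq_2x2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(obs)
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) return(NA_real_)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

# Exact two-category goodness-of-fit tail probability by binomial
# enumeration: P(X2(k) >= x2_obs) for counts k ~ Binom(n, p1).
oracle_exact_gof_p <- function(obs, p1 = 0.5) {
  n <- sum(obs)
  e <- n * c(p1, 1 - p1)
  x2 <- function(k) (k - e[1])^2 / e[1] + (n - k - e[2])^2 / e[2]
  x2_obs <- x2(obs[1])
  k <- 0:n
  sum(stats::dbinom(k[x2(k) >= x2_obs - 1e-9], n, p1))
}

# Minimal fold-change table for call_copy_number tests.
make_fc <- function(fc_ex2, fc_ex4,
                    status_ex2 = ifelse(is.na(fc_ex2), "absent", "ok"),
                    status_ex4 = ifelse(is.na(fc_ex4), "absent", "ok"),
                    reference_status = "ok") {
  tibble::tibble(
    sample = paste0("s", seq_along(fc_ex2)), run = "run1",
    reference_status = reference_status,
    fc_ex2 = fc_ex2, fc_ex4 = fc_ex4,
    status_ex2 = status_ex2, status_ex4 = status_ex4
  )
}

# Long genotype rows for one individual from allele pairs.
geno_rows <- function(id, ...) {
  alleles <- list(...)
  tibble::tibble(
    id = id,
    marker = paste0("m", seq_along(alleles)),
    allele1 = as.character(vapply(alleles, function(a) as.character(a)[1], "")),
    allele2 = as.character(vapply(alleles, function(a) as.character(a)[2], ""))
  )
}
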