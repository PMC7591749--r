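trio_geno <- function(off, sire, dam) {
  dplyr::bind_rows(geno_rows("o", off), geno_rows("s", sire),
                   geno_rows("d", dam))
}
trio_ped <- tibble::tibble(id = "o", sire = "s", dam = "d", family = "f1")

test_that("single-marker transmission deduction covers the canonical trios", {
  tr <- infer_transmission(trio_geno(c("A", "C"), c("A", "B"), c("C", "C")),
                           trio_ped)
  expect_equal(tr$paternal_allele, "A")
  expect_equal(tr$maternal_allele, "C")
  expect_equal(tr$resolved_by, "single_marker")

  # fully heterozygous trio is phase-ambiguous
  tr2 <- infer_transmission(trio_geno(c("A", "B"), c("A", "B"), c("A", "B")),
                            trio_ped)
  expect_equal(tr2$status, "unresolved")
  expect_true(is.na(tr2$paternal_allele))

  # homozygous sire resolves trivially (monomorphic transmission)
  tr3 <- infer_transmission(trio_geno(c("A", "B"), c("A", "A"), c("B", "B")),
                            trio_ped)
  expect_equal(tr3$paternal_allele, "A")
  expect_equal(tr3$maternal_allele, "B")

  # offspring allele present in neither parent
  tr4 <- infer_transmission(trio_geno(c("C", "A"), c("A", "B"), c("A", "B")),
                            trio_ped)
  expect_equal(tr4$status, "mendelian_error")

  tr5 <- infer_transmission(trio_geno(c("A", NA), c("A", "B"), c("A", "B")),
                            trio_ped)
  expect_equal(tr5$status, "missing")
})

test_that("phase rescue recovers transmissions consistent with the true gametes", {
  map <- tibble::tibble(marker = paste0("m", 1:6), chromosome = "c1",
                        cM = c(0, 2, 4, 6, 8, 10))
  # sire heterozygous everywhere; dam homozygous at odd markers, so the
  # even (doubly heterozygous) markers produce phase-ambiguous trios that
  # the odd markers can rescue on the sire side
  haps_s <- matrix(c(rep("A", 6), rep("B", 6)), 6, 2,
                   dimnames = list(map$marker, NULL))
  haps_d <- matrix(c("A", "A", "A", "A", "A", "A",
                     "A", "B", "A", "B", "A", "B"), 6, 2,
                   dimnames = list(map$marker, NULL))
  n <- 40
  withr::with_seed(13, {
    pat <- simulate_gametes(haps_s, map, n)
    mat <- simulate_gametes(haps_d, map, n)
  })
  off_ids <- sprintf("o%02d", 1:n)
  geno <- dplyr::bind_rows(
    tibble::tibble(id = "s", marker = map$marker,
                   allele1 = haps_s[, 1], allele2 = haps_s[, 2]),
    tibble::tibble(id = "d", marker = map$marker,
                   allele1 = haps_d[, 1], allele2 = haps_d[, 2]),
    purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(id = off_ids[i], marker = map$marker,
                     allele1 = pat$alleles[, i], allele2 = mat$alleles[, i])
    })
  )
  ped <- tibble::tibble(id = off_ids, sire = "s", dam = "d", family = "f1")
  tr <- infer_transmission(geno, ped, map = map)
  rescued <- dplyr::filter(tr, resolved_by == "phase")
  expect_gt(nrow(rescued), 0)
  truth_pat <- pat$alleles[cbind(match(rescued$marker, map$marker),
                                 match(rescued$offspring_id, off_ids))]
  # imputation errors require a recombination within a few cM: rare
  expect_gte(mean(rescued$paternal_allele == truth_pat), 0.95)
  # without the rescue all both-het trios with het offspring stay unresolved
  tr0 <- infer_transmission(geno, ped, resolve_phase = FALSE)
  expect_gt(sum(tr0$status == "unresolved"), sum(tr$status == "unresolved"))
})

test_that("phase rescue refuses the symmetric all-heterozygous family", {
  # when both parents are A/B at every marker the paternal and maternal
  # recombination paths cannot be told apart, so nothing may be rescued
  map <- tibble::tibble(marker = paste0("m", 1:4), chromosome = "c1",
                        cM = c(0, 2, 4, 6))
  haps <- matrix(c(rep("A", 4), rep("B", 4)), 4, 2,
                 dimnames = list(map$marker, NULL))
  n <- 20
  withr::with_seed(14, {
    pat <- simulate_gametes(haps, map, n)
    mat <- simulate_gametes(haps, map, n)
  })
  off_ids <- sprintf("o%02d", 1:n)
  geno <- dplyr::bind_rows(
    tibble::tibble(id = c("s", "d")) |>
      tidyr::crossing(tibble::tibble(marker = map$marker)) |>
      dplyr::mutate(allele1 = "A", allele2 = "B"),
    purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(id = off_ids[i], marker = map$marker,
                     allele1 = pat$alleles[, i], allele2 = mat$alleles[, i])
    })
  )
  ped <- tibble::tibble(id = off_ids, sire = "s", dam = "d", family = "f1")
  tr <- infer_transmission(geno, ped, map = map)
  expect_equal(sum(tr$resolved_by == "phase", na.rm = TRUE), 0)
})

test_that("scan statistics match hand-computed 2x2 chi-squared values", {
  # 10 discordant offspring all inherited A, 10 concordant all inherited B
  n <- 20
  off <- sprintf("o%02d", 1:n)
  geno <- dplyr::bind_rows(
    tibble::tibble(id = "s", marker = "m1", allele1 = "A", allele2 = "B"),
    tibble::tibble(id = "d", marker = "m1", allele1 = "C", allele2 = "C"),
    tibble::tibble(id = off, marker = "m1",
                   allele1 = rep(c("A", "B"), each = 10), allele2 = "C")
  )
  ped <- tibble::tibble(id = off, sire = "s", dam = "d", family = "f1")
  map <- tibble::tibble(marker = "m1", chromosome = "c9", cM = 5)
  tr <- infer_transmission(geno, ped)
  pheno <- tibble::tibble(id = off, class = rep(c("disc", "conc"), each = 10))
  sc <- scan_trait(tr, pheno, geno, map, trait = "discordance")
  sire_row <- dplyr::filter(sc, parent == "sire")
  expect_equal(sire_row$chi_sq, 20)
  expect_equal(sire_row$n_informative, 20L)
  expect_equal(sire_row$p_value, stats::pchisq(20, 1, lower.tail = FALSE))
  # the homozygous dam is never scanned
  expect_false("dam" %in% sc$parent)

  # independence gives a zero statistic
  pheno2 <- tibble::tibble(id = off, class = rep(c("disc", "conc"), 10))
  sc2 <- scan_trait(tr, pheno2, geno, map, trait = "discordance")
  expect_equal(dplyr::filter(sc2, parent == "sire")$chi_sq, 0)
})

test_that("package chi-squared equals the contingency oracle on all small tables", {
  for (n in 2:12) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    parts$d <- n - rowSums(parts)
    got <- sdyped:::.chisq_2x2(parts$a, parts$b, parts$c, parts$d)
    want <- mapply(oracle_chisq_2x2, parts$a, parts$b, parts$c, parts$d)
    expect_equal(got, unname(want))
  }
})

test_that("mendelian-inconsistent trios never enter a contingency table", {
  off <- c("o1", "o2", "o3")
  geno <- dplyr::bind_rows(
    tibble::tibble(id = "s", marker = "m1", allele1 = "A", allele2 = "B"),
    tibble::tibble(id = "d", marker = "m1", allele1 = "C", allele2 = "C"),
    tibble::tibble(id = off, marker = "m1",
                   allele1 = c("A", "B", "E"), allele2 = c("C", "C", "E"))
  )
  ped <- tibble::tibble(id = off, sire = "s", dam = "d", family = "f1")
  map <- tibble::tibble(marker = "m1", chromosome = "c1", cM = 0)
  tr <- infer_transmission(geno, ped)
  expect_equal(tr$status[tr$offspring_id == "o3"], "mendelian_error")
  pheno <- tibble::tibble(id = off, class = c("x", "y", "x"))
  sc <- scan_trait(tr, pheno, geno, map)
  expect_equal(dplyr::filter(sc, parent == "sire")$n_informative, 2L)
})

test_that("the sex scan localises the simulated sex-determining chromosome", {
  cfg <- sdy_sim_config(n_families = 10, offspring_per_family = 30)
  st <- generate_study(cfg, seed = 61)
  ped <- dplyr::filter(st$pedigree, generation == "F1")
  tr <- infer_transmission(st$genotypes_snp, st$pedigree, map = st$linkage_map)
  sc <- scan_trait(tr, tibble::tibble(id = ped$id, class = ped$phenotypic_sex),
                   st$genotypes_snp, st$linkage_map, trait = "sex")
  sm <- summarize_scan(sc)
  expect_gte(mean(sm$top_chromosome == "Ssa02"), 0.8)
})

test_that("scan summaries handle single markers and unmappable families", {
  sc <- tibble::tibble(
    trait = "sex", family = c("f1", "f2"), marker = c("m1", "m2"),
    chromosome = c("c3", "c4"), cM = c(1, 2), parent = "sire",
    n11 = c(5L, 0L), n12 = c(0L, 0L), n21 = c(0L, 0L), n22 = c(5L, 2L),
    n_informative = c(10L, 2L), chi_sq = c(10, NA),
    p_value = c(stats::pchisq(10, 1, lower.tail = FALSE), NA),
    reason = c(NA, "single phenotype class")
  )
  class(sc) <- c("sdy_scan", class(sc))
  sm <- summarize_scan(sc)
  expect_equal(sm$top_chromosome[sm$family == "f1"], "c3")
  expect_false(sm$mappable[sm$family == "f2"])
  expect_true(is.na(sm$top_marker[sm$family == "f2"]))
})
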