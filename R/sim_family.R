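# Internal: phased haplotypes for one parent, including the two special loci.
# The Y-linked sdY locus ("__sdy__") and the autosomal pseudocopy locus
# ("__pseudo__") ride along the gene-drop walk exactly like SNPs, so both are
# transmitted Mendelianly and are linked to the SNPs of their chromosome.
.augmented_map <- function(config) {
  bind_rows(
    config$map,
    tibble(marker = "__sdy__", chromosome = config$sd_chromosome,
           cM = config$sd_position),
    tibble(marker = "__pseudo__", chromosome = config$pseudo_chromosome,
           cM = config$pseudo_position)
  ) %>%
    arrange(.data$chromosome, .data$cM)
}

.sim_parent_haplotypes <- function(config, y_copies, auto_alleles) {
  m <- nrow(config$map)
  snp <- matrix(
    ifelse(runif(2 * m) < config$snp_maf, "A", "B"), m, 2,
    dimnames = list(config$map$marker, NULL)
  )
  sdy_row <- switch(as.character(y_copies),
    "0" = c("-", "-"), "1" = c("Y", "-"), "2" = c("Y", "Y"))
  pseudo_row <- switch(as.character(auto_alleles),
    "0" = c("0", "0"),
    "1" = if (runif(1) < 0.5) c("1", "0") else c("0", "1"),
    "2" = c("1", "1"))
  rbind(snp, `__sdy__` = sdy_row, `__pseudo__` = pseudo_row)
}

.sim_parent_msat <- function(config) {
  matrix(
    sprintf("a%d", sample.int(config$msat_alleles, 2 * config$n_msat,
                              replace = TRUE)),
    config$n_msat, 2,
    dimnames = list(sprintf("msat%d", seq_len(config$n_msat)), NULL)
  )
}

.geno_long <- function(id, allele1, allele2, markers) {
  ids <- rep(id, each = length(markers))
  mks <- rep(markers, length(id))
  tibble(id = ids, marker = mks,
         allele1 = as.vector(allele1), allele2 = as.vector(allele2))
}

#' Simulate one full-sib family under the autosomal pseudocopy model
#'
#' Draws offspring of a standard XY sire x XX dam cross. Offspring sex is
#' determined solely by transmission of the sire's Y-linked sdY copy
#' (probability 1/2); autosomal pseudocopy alleles are transmitted through
#' the gene-drop meiosis of the pseudocopy chromosome, so their marginal
#' transmission probability is `allele count / 2` per gamete and they
#' co-segregate with SNPs on that chromosome. Phenotypic sex equals genetic
#' sex (the pseudocopy is non-functional).
#'
#' @param sire_auto,dam_auto Pseudocopy allele counts (0, 1 or 2) of the sire
#'   and the dam. The sire carries exactly one Y-linked copy, the dam none.
#' @param config An [sdy_sim_config()].
#' @param family_id Family label used in ids.
#' @param n Number of offspring (default `config$offspring_per_family`).
#' @param markers Also simulate SNP and microsatellite genotypes. With
#'   `FALSE` only the pedigree and true sdY genotypes are produced (the
#'   pseudocopy and sdY loci are still transmitted by meiosis).
#' @return A list with tibbles `pedigree` (id, sire, dam, family,
#'   phenotypic_sex, generation), `truth` (id, y_copies, auto_copies,
#'   family), and, when `markers = TRUE`, long-format `genotypes_snp` and
#'   `genotypes_msat` for parents and offspring.
#' @examples
#' cfg <- sdy_sim_config(n_families = 1, offspring_per_family = 8)
#' withr::with_seed(1, simulate_family(0, 1, cfg))$truth
#' @export
simulate_family <- function(sire_auto, dam_auto, config = sdy_sim_config(),
                            family_id = "F01",
                            n = config$offspring_per_family,
                            markers = TRUE) {
  stopifnot(sire_auto %in% 0:2, dam_auto %in% 0:2, n >= 1)
  amap <- .augmented_map(config)
  sire_id <- paste0(family_id, "_S")
  dam_id <- paste0(family_id, "_D")
  off_id <- sprintf("%s_O%03d", family_id, seq_len(n))

  sire_h <- .sim_parent_haplotypes(config, y_copies = 1, auto_alleles = sire_auto)
  dam_h <- .sim_parent_haplotypes(config, y_copies = 0, auto_alleles = dam_auto)
  pat <- simulate_gametes(sire_h, amap, n,
                          map_scale = config$male_recombination_ratio)$alleles
  mat <- simulate_gametes(dam_h, amap, n)$alleles

  y_off <- as.integer(pat["__sdy__", ] == "Y")
  auto_off <- as.integer(pat["__pseudo__", ] == "1") +
    as.integer(mat["__pseudo__", ] == "1")
  sex_off <- ifelse(y_off == 1, "M", "F")

  pedigree <- bind_rows(
    tibble(id = c(sire_id, dam_id), sire = NA_character_, dam = NA_character_,
           family = family_id, phenotypic_sex = c("M", "F"), generation = "P"),
    tibble(id = off_id, sire = sire_id, dam = dam_id, family = family_id,
           phenotypic_sex = sex_off, generation = "F1")
  )
  truth <- tibble(
    id = c(sire_id, dam_id, off_id),
    y_copies = c(1L, 0L, y_off),
    auto_copies = c(as.integer(sire_auto), as.integer(dam_auto), auto_off),
    family = family_id
  )
  out <- list(pedigree = pedigree, truth = truth)
  if (!markers) return(out)

  snp_markers <- config$map$marker
  out$genotypes_snp <- bind_rows(
    .geno_long(c(sire_id, dam_id),
               cbind(sire_h[snp_markers, 1], dam_h[snp_markers, 1]),
               cbind(sire_h[snp_markers, 2], dam_h[snp_markers, 2]),
               snp_markers),
    .geno_long(off_id, pat[snp_markers, , drop = FALSE],
               mat[snp_markers, , drop = FALSE], snp_markers)
  )

  # microsatellites are unlinked: each locus segregates independently
  sire_ms <- .sim_parent_msat(config)
  dam_ms <- .sim_parent_msat(config)
  pick <- function(h) {
    sel <- matrix(sample.int(2L, config$n_msat * n, replace = TRUE),
                  config$n_msat, n)
    matrix(h[cbind(rep(seq_len(config$n_msat), n), as.vector(sel))],
           config$n_msat, n)
  }
  out$genotypes_msat <- bind_rows(
    .geno_long(c(sire_id, dam_id), cbind(sire_ms[, 1], dam_ms[, 1]),
               cbind(sire_ms[, 2], dam_ms[, 2]), rownames(sire_ms)),
    .geno_long(off_id, pick(sire_ms), pick(dam_ms), rownames(sire_ms))
  )
  out
}
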