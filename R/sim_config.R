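#' Build an evenly spaced SNP linkage map
#'
#' Distributes `n_markers` SNPs as evenly as possible over the supplied
#' chromosomes, spacing them uniformly along each chromosome. The default
#' emulates a genome-wide panel of 109 SNPs over the 29 Atlantic salmon
#' chromosome pairs (Ssa01--Ssa29).
#'
#' @param n_markers Number of SNP markers in the panel.
#' @param chromosomes Character vector of chromosome labels.
#' @param chromosome_length Genetic length of each chromosome in centimorgans
#'   (a single value recycled over chromosomes).
#' @return A tibble with columns `marker`, `chromosome`, `cM`; positions are
#'   non-decreasing within a chromosome and marker ids are unique.
#' @examples
#' sim_linkage_map(10, c("chr1", "chr2"), 100)
#' @export
sim_linkage_map <- function(n_markers = 109,
                            chromosomes = sprintf("Ssa%02d", 1:29),
                            chromosome_length = 100) {
  stopifnot(n_markers >= 1, length(chromosomes) >= 1, !anyDuplicated(chromosomes))
  len <- rep_len(chromosome_length, length(chromosomes))
  per <- rep(n_markers %/% length(chromosomes), length(chromosomes))
  extra <- n_markers %% length(chromosomes)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  map <- map_dfr(seq_along(chromosomes), function(i) {
    k <- per[i]
    if (k == 0) return(tibble())
    tibble(
      chromosome = chromosomes[i],
      cM = len[i] * (seq_len(k) - 0.5) / k
    )
  })
  map$marker <- sprintf("snp%03d", seq_len(nrow(map)))
  map[, c("marker", "chromosome", "cM")]
}

#' Default carrier-parent layout for a simulated cross design
#'
#' Mirrors the structure reported for a 64-family study in which eight
#' families segregated an autosomal sdY pseudocopy: five through a carrier
#' sire only, two through both a carrier sire and a carrier dam, and one
#' through a carrier dam only. All carriers are heterozygous (one pseudocopy
#' allele).
#'
#' @param family_ids Character vector of family identifiers.
#' @return Tibble with columns `family`, `sire_auto`, `dam_auto` (pseudocopy
#'   allele counts in 0..2); families not listed carry none.
#' @export
default_carriers <- function(family_ids) {
  n <- length(family_ids)
  idx_sire <- seq_len(min(7, n))             # families 1-7 have a carrier sire
  idx_dam  <- intersect(6:8, seq_len(n))     # families 6-8 have a carrier dam
  aff <- sort(union(idx_sire, idx_dam))
  tibble(
    family = family_ids[aff],
    sire_auto = as.integer(aff %in% idx_sire),
    dam_auto = as.integer(aff %in% idx_dam)
  )
}

#' Configuration for the synthetic study generator
#'
#' Collects every parameter of the simulated cross design: pedigree size,
#' marker panels, the genomic placement of the Y-linked sdY locus and of the
#' autosomal pseudocopy locus, which parents carry pseudocopy alleles, and
#' the qPCR noise model.
#'
#' @param n_families Number of full-sib families (each with its own sire and
#'   dam).
#' @param offspring_per_family Offspring per family.
#' @param map SNP linkage map as returned by [sim_linkage_map()].
#' @param n_msat,msat_alleles Microsatellite parentage panel: number of
#'   unlinked loci and number of equifrequent alleles per locus.
#' @param snp_maf Allele frequency used for every SNP (biallelic, alleles
#'   "A"/"B").
#' @param sd_chromosome,sd_position Chromosome and cM position of the
#'   Y-linked sdY sex-determining locus.
#' @param pseudo_chromosome,pseudo_position Chromosome and cM position of the
#'   autosomal pseudocopy locus. Must differ from `sd_chromosome` unless
#'   `linked_pseudo = TRUE`.
#' @param linked_pseudo Place the pseudocopy locus on the sex-determining
#'   chromosome (the "family F12" situation where sex and discordance map to
#'   the same chromosome).
#' @param male_recombination_ratio Ratio of male to female map distances
#'   used for sire meioses (heterochiasmy); Atlantic salmon males recombine
#'   far less than females, with reported female:male ratios of roughly
#'   4--8, hence the default of 0.25.
#' @param carriers Tibble (`family`, `sire_auto`, `dam_auto`) of pseudocopy
#'   allele counts per carrier parent; defaults to [default_carriers()].
#' @param ct_noise_sd Gaussian standard deviation (cycles) applied
#'   independently to every simulated Ct measurement.
#' @param ct_reference_mean Mean Ct of the reference gene (and of a one-copy
#'   sdY amplicon) in cycles.
#' @param n_replicates qPCR replicates per sample and target.
#' @param dropout_ct_cutoff Simulated Ct above this value is censored to
#'   "no amplification".
#' @param n_reference_males Number of extra one-copy XY males simulated as
#'   the fold-change calibrator panel.
#' @return A list of class `sdy_sim_config`.
#' @seealso [generate_study()]
#' @export
sdy_sim_config <- function(n_families = 64,
                           offspring_per_family = 32,
                           map = sim_linkage_map(),
                           n_msat = 6,
                           msat_alleles = 8,
                           snp_maf = 0.5,
                           sd_chromosome = "Ssa02",
                           sd_position = 40,
                           pseudo_chromosome = "Ssa05",
                           pseudo_position = 40,
                           linked_pseudo = FALSE,
                           male_recombination_ratio = 0.25,
                           carriers = NULL,
                           ct_noise_sd = 0.15,
                           ct_reference_mean = 25,
                           n_replicates = 2,
                           dropout_ct_cutoff = 40,
                           n_reference_males = 10) {
  stopifnot(
    n_families >= 1, offspring_per_family >= 1,
    is.data.frame(map), all(c("marker", "chromosome", "cM") %in% names(map)),
    !anyDuplicated(map$marker),
    n_msat >= 1, msat_alleles >= 2,
    snp_maf > 0, snp_maf < 1,
    ct_noise_sd >= 0, n_replicates >= 1,
    male_recombination_ratio > 0, male_recombination_ratio <= 1
  )
  if (linked_pseudo) pseudo_chromosome <- sd_chromosome
  if (identical(pseudo_chromosome, sd_chromosome) && !linked_pseudo) {
    abort("pseudo_chromosome may equal sd_chromosome only with linked_pseudo = TRUE")
  }
  family_ids <- sprintf("F%02d", seq_len(n_families))
  if (is.null(carriers)) carriers <- default_carriers(family_ids)
  stopifnot(
    all(c("family", "sire_auto", "dam_auto") %in% names(carriers)),
    all(carriers$family %in% family_ids),
    all(carriers$sire_auto %in% 0:2), all(carriers$dam_auto %in% 0:2)
  )
  structure(
    list(
      n_families = as.integer(n_families),
      offspring_per_family = as.integer(offspring_per_family),
      family_ids = family_ids,
      map = as_tibble(map),
      n_msat = as.integer(n_msat),
      msat_alleles = as.integer(msat_alleles),
      snp_maf = snp_maf,
      sd_chromosome = sd_chromosome,
      sd_position = sd_position,
      pseudo_chromosome = pseudo_chromosome,
      pseudo_position = pseudo_position,
      linked_pseudo = linked_pseudo,
      male_recombination_ratio = male_recombination_ratio,
      carriers = as_tibble(carriers),
      ct_noise_sd = ct_noise_sd,
      ct_reference_mean = ct_reference_mean,
      n_replicates = as.integer(n_replicates),
      dropout_ct_cutoff = dropout_ct_cutoff,
      n_reference_males = as.integer(n_reference_males)
    ),
    class = "sdy_sim_config"
  )
}

#' @export
print.sdy_sim_config <- function(x, ...) {
  cat("<sdy_sim_config>\n")
  cat(sprintf("  %d families x %d offspring; %d SNPs on %d chromosomes; %d msat loci\n",
              x$n_families, x$offspring_per_family, nrow(x$map),
              length(unique(x$map$chromosome)), x$n_msat))
  cat(sprintf("  sdY locus: %s @ %g cM; pseudocopy locus: %s @ %g cM%s\n",
              x$sd_chromosome, x$sd_position, x$pseudo_chromosome,
              x$pseudo_position, if (x$linked_pseudo) " (linked mode)" else ""))
  cat(sprintf("  carriers: %d families; qPCR noise sd %g cycles, %d replicates\n",
              nrow(x$carriers), x$ct_noise_sd, x$n_replicates))
  invisible(x)
}
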