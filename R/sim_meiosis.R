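#' Haldane map function
#'
#' Converts a genetic map distance into a recombination fraction assuming no
#' crossover interference: `r = (1 - exp(-2 d / 100)) / 2` for `d` in
#' centimorgans. `r` is 0 at `d = 0` and approaches 1/2 as loci become
#' unlinked.
#'
#' @param d Map distance in centimorgans (non-negative, vectorised).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane(c(0, 10, 50, 1e6))
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d / 100)) / 2
}

#' Simulate gametes from a phased parent by gene drop
#'
#' Performs a gene-drop walk along each chromosome of the map: the starting
#' haplotype is chosen uniformly and the walk switches haplotype between
#' adjacent markers with probability given by the Haldane map function of
#' their distance. Chromosomes segregate independently.
#'
#' @param haplotypes Matrix with one row per map marker (rownames = marker
#'   ids) and two columns, the parent's two phased haplotypes.
#' @param map Tibble (`marker`, `chromosome`, `cM`) ordered by chromosome and
#'   position; every map marker must be present in `haplotypes`.
#' @param n Number of gametes to draw.
#' @param map_scale Multiplier applied to map distances before the Haldane
#'   conversion; used to model heterochiasmy (male meioses in salmonids
#'   recombine far less than female ones).
#' @return A list with `alleles` (markers x n matrix of transmitted alleles)
#'   and `haplotype` (markers x n integer matrix, 1 or 2, the parental
#'   haplotype of origin at each marker).
#' @export
simulate_gametes <- function(haplotypes, map, n = 1, map_scale = 1) {
  stopifnot(is.matrix(haplotypes), ncol(haplotypes) == 2, n >= 1)
  if (!all(map$marker %in% rownames(haplotypes))) {
    abort("parent is not phased at all map markers")
  }
  map <- arrange(map, .data$chromosome, .data$cM)
  m <- nrow(map)
  hap <- matrix(0L, m, n)
  idx_by_chr <- split(seq_len(m), map$chromosome)
  for (idx in idx_by_chr) {
    k <- length(idx)
    start <- sample.int(2L, n, replace = TRUE) - 1L
    if (k == 1) {
      hap[idx, ] <- start
      next
    }
    r <- haldane(map_scale * diff(map$cM[idx]))
    # column-major fill: the (k-1)-long prob vector recycles once per gamete
    sw <- matrix(rbinom((k - 1) * n, 1L, rep(r, n)), k - 1, n)
    cum <- apply(sw, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = k - 1)
    hap[idx, ] <- (matrix(start, k, n, byrow = TRUE) + rbind(0L, cum)) %% 2L
  }
  hap <- hap + 1L
  h <- haplotypes[map$marker, , drop = FALSE]
  alleles <- matrix(h[cbind(rep(seq_len(m), n), as.vector(hap))], m, n,
                    dimnames = list(map$marker, NULL))
  list(alleles = alleles, haplotype = `dimnames<-`(hap, list(map$marker, NULL)))
}

#' Simulate a single meiosis
#'
#' Convenience wrapper around [simulate_gametes()] returning one gamete as a
#' named allele vector.
#'
#' @inheritParams simulate_gametes
#' @return Named vector of transmitted alleles, one per map marker.
#' @export
simulate_meiosis <- function(haplotypes, map) {
  g <- simulate_gametes(haplotypes, map, n = 1)
  setNames(g$alleles[, 1], rownames(g$alleles))
}
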