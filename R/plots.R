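#' Fold-change validation plot
#'
#' Scatter of the two sdY amplicon fold changes per sample, with the
#' copy-number band edges drawn as reference lines; points are coloured by
#' the integer copy-number call when one is supplied. Samples in which an
#' amplicon did not amplify are plotted at 0 on that axis.
#'
#' @param fc Fold-change table from [compute_fold_change()].
#' @param calls Optional calls from [call_copy_number()].
#' @param bands Band edges from [sdy_bands()].
#' @return A ggplot object.
#' @export
plot_fold_change <- function(fc, calls = NULL, bands = sdy_bands()) {
  dat <- fc %>%
    mutate(fc_ex2 = ifelse(is.na(.data$fc_ex2), 0, .data$fc_ex2),
           fc_ex4 = ifelse(is.na(.data$fc_ex4), 0, .data$fc_ex4))
  if (!is.null(calls)) {
    dat <- left_join(dat, select(calls, "sample", "copies", call_status = "status"),
                     by = "sample") %>%
      mutate(copies = factor(ifelse(is.na(.data$copies), "no call",
                                    as.character(.data$copies))))
  }
  edges <- unlist(bands[c("one_two", "two_three")])
  p <- ggplot(dat, aes(x = .data$fc_ex2, y = .data$fc_ex4)) +
    geom_hline(yintercept = edges, linetype = "dashed", colour = "grey60") +
    geom_vline(xintercept = edges, linetype = "dashed", colour = "grey60") +
    labs(x = "fold change, sdY exon 2", y = "fold change, sdY exon 4") +
    theme_bw()
  if (!is.null(calls)) {
    p + geom_point(aes(colour = .data$copies), alpha = 0.8) +
      scale_colour_brewer(palette = "Dark2", name = "sdY copies")
  } else {
    p + geom_point(alpha = 0.8)
  }
}

#' Expected offspring distribution plot
#'
#' Bar chart of the expected (sex x total copy number) probabilities for a
#' cross, as returned by [offspring_distribution()].
#'
#' @param dist Tibble from [offspring_distribution()].
#' @return A ggplot object.
#' @export
plot_offspring_distribution <- function(dist) {
  ggplot(dist, aes(x = factor(.data$total_copies), y = .data$prob)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~sex, labeller = ggplot2::labeller(
      sex = c(F = "females", M = "males"))) +
    labs(x = "total sdY copies", y = "expected proportion") +
    theme_bw()
}

#' @describeIn scan_trait Manhattan-style plot of a linkage scan:
#'   `-log10(p)` by map position, faceted by chromosome and coloured by
#'   trait.
#' @param object An `sdy_scan` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sdy_scan <- function(object, ...) {
  dat <- filter(object, !is.na(.data$chi_sq))
  ggplot(dat, aes(x = .data$cM, y = -log10(.data$p_value),
                  colour = .data$trait)) +
    geom_point(size = 0.8) +
    facet_wrap(~chromosome) +
    labs(x = "position (cM)", y = expression(-log[10](p))) +
    theme_bw()
}
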