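#' Scatterplot of per-gene RPM between two samples
#'
#' Log-log scatter of test versus reference RPM with genes past the fold
#' threshold highlighted, mirroring the standard differential small-RNA
#' scatterplots. Requires ggplot2.
#'
#' @param diff A [DifferentialResult-class].
#' @param test,ref The [CountTable-class] pair the result was computed
#'   from.
#' @param pseudo Pseudocount added for log display only. Default 0.1 RPM.
#' @return A ggplot object.
#' @export
plotDifferentialScatter <- function(diff, test, ref, pseudo = 0.1) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("ggplot2 is required for plotting", call. = FALSE)
    ids <- geneIds(diff)
    df <- data.frame(test = rpm(test)[ids] + pseudo,
                     ref = rpm(ref)[ids] + pseudo,
                     category = categories(diff)[ids])
    ggplot2::ggplot(df, ggplot2::aes(x = ref, y = test,
                                     colour = category)) +
        ggplot2::geom_point(size = 0.8, alpha = 0.6) +
        ggplot2::geom_abline(slope = 1, intercept = 0,
                             linetype = "dashed") +
        ggplot2::geom_abline(slope = 1, intercept = log10(diff@fold),
                             linetype = "dotted") +
        ggplot2::geom_abline(slope = 1, intercept = -log10(diff@fold),
                             linetype = "dotted") +
        ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
        ggplot2::scale_colour_manual(values = c(
            up = "firebrick", down = "steelblue", unchanged = "grey60",
            below_floor = "grey85")) +
        ggplot2::labs(x = paste0(diff@refSample, " (RPM)"),
                      y = paste0(diff@testSample, " (RPM)"))
}

#' Overlay metagene profiles as line charts
#'
#' @param profiles Named list of [MetageneProfile-class] objects.
#' @return A ggplot object (x: percent of transcript length 5' to 3';
#'   y: aggregated coverage).
#' @export
plotMetagene <- function(profiles) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("ggplot2 is required for plotting", call. = FALSE)
    if (is(profiles, "MetageneProfile")) profiles <- list(profile = profiles)
    df <- do.call(rbind, lapply(names(profiles), function(nm)
        data.frame(profile = nm, bin = 1:100,
                   value = profileBins(profiles[[nm]]))))
    ggplot2::ggplot(df, ggplot2::aes(x = bin, y = value,
                                     colour = profile)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "percent of transcript length (5' to 3')",
                      y = "aggregated coverage")
}
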