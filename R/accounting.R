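#' Membership matrix of removed variants
#'
#' Reduces a verdict data.frame (as produced by \code{\link{applyMethod}})
#' to the removed variants only: a logical matrix with one row per removed
#' variant and one column per filter label, TRUE where that filter removed
#' the variant. Kept variants (all-FALSE rows) are excluded.
#'
#' @param verdicts data.frame with a \code{key} column and one logical
#'   column per filter label.
#' @return logical matrix (removed variants x labels), rownames = keys.
#' @export
filterMembership <- function(verdicts) {
    stopifnot("key" %in% names(verdicts))
    m <- as.matrix(verdicts[, setdiff(names(verdicts), "key"), drop = FALSE])
    storage.mode(m) <- "logical"
    rownames(m) <- verdicts$key
    m[rowSums(m) > 0L, , drop = FALSE]
}

#' Exclusive intersection counts (UpSet semantics)
#'
#' Groups removed variants by their EXACT failed-filter combination, the
#' exclusive-intersection convention of UpSet plots: a variant removed by
#' both the tumor-AD filter and the pool filter counts toward the
#' \{ADt, pool\} bar only, not toward the singleton bars. Combinations with
#' fewer than \code{minCount} members are marked as not displayed but are
#' always retained in the returned table, so the counts still partition the
#' removed variants.
#'
#' @param membership logical matrix from \code{\link{filterMembership}}.
#' @param minCount display-suppression threshold (default 15).
#' @return data.frame with \code{labels} (combination as "A&B" string),
#'   \code{count}, \code{displayed}; ordered by decreasing count. The
#'   attribute \code{"marginals"} carries the per-label inclusive totals.
#' @export
exclusiveIntersectionCounts <- function(membership, minCount = 15L) {
    labs <- colnames(membership)
    if (nrow(membership) == 0L) {
        out <- data.frame(labels = character(0), count = integer(0),
                          displayed = logical(0))
        attr(out, "marginals") <- setNames(integer(length(labs)), labs)
        return(out)
    }
    combo <- apply(membership, 1L, function(r) paste(labs[r], collapse = "&"))
    tab <- table(combo)
    out <- data.frame(labels = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$labels), , drop = FALSE]
    rownames(out) <- NULL
    out$displayed <- out$count >= minCount
    attr(out, "marginals") <- colSums(membership)
    out
}

#' Per-label marginal removal counts
#'
#' For each filter label, the number of removed variants that label
#' contributed to (inclusive count); equals the sum of exclusive counts of
#' every combination containing the label.
#'
#' @param membership logical matrix from \code{\link{filterMembership}}.
#' @return named integer vector.
#' @export
filterMarginals <- function(membership) colSums(membership)

#' Base-graphics UpSet-style plot of filter overlaps
#'
#' Convenience display of \code{\link{exclusiveIntersectionCounts}}: bars of
#' exclusive combination sizes over a dot matrix of the combinations.
#' Combinations below \code{minCount} are suppressed, mirroring the usual
#' presentation.
#'
#' @param membership logical matrix from \code{\link{filterMembership}}.
#' @param minCount suppress combinations with fewer variants than this.
#' @param main plot title.
#' @return the displayed counts data.frame, invisibly.
#' @export
plotFilterUpset <- function(membership, minCount = 15L, main = "Filter overlap") {
    cnt <- exclusiveIntersectionCounts(membership, minCount)
    shown <- cnt[cnt$displayed, , drop = FALSE]
    if (nrow(shown) == 0L) {
        warning("no combination reaches minCount; nothing to plot")
        return(invisible(shown))
    }
    labs <- colnames(membership)
    oldPar <- graphics::par(no.readonly = TRUE)
    on.exit(graphics::par(oldPar))
    graphics::par(mfrow = c(2, 1), mar = c(0.5, 8, 3, 1))
    bp <- graphics::barplot(shown$count, ylab = "variants removed",
                            main = main, col = "grey30", border = NA)
    graphics::text(bp, shown$count, labels = shown$count, pos = 3,
                   xpd = NA, cex = 0.8)
    graphics::par(mar = c(1, 8, 0.5, 1))
    graphics::plot(NA, xlim = range(bp) + c(-0.5, 0.5),
                   ylim = c(length(labs) + 0.5, 0.5), axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(2, at = seq_along(labs), labels = labs, las = 2,
                   tick = FALSE)
    for (i in seq_len(nrow(shown))) {
        members <- strsplit(shown$labels[i], "&", fixed = TRUE)[[1L]]
        y <- match(members, labs)
        graphics::points(rep(bp[i], length(labs)), seq_along(labs),
                         pch = 19, col = "grey85", cex = 1.2)
        graphics::points(rep(bp[i], length(y)), y, pch = 19, cex = 1.2)
        if (length(y) > 1L)
            graphics::segments(bp[i], min(y), bp[i], max(y), lwd = 2)
    }
    invisible(shown)
}
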