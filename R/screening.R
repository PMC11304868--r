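#' Filter features by VIP score
#'
#' Strictly-greater-than threshold filter (the conventional VIP > 1.0
#' screen), returning marker names ordered by descending VIP.
#'
#' @param vip_scores Named numeric vector of VIP scores (finite).
#' @param threshold Cutoff (default 1.0, strict inequality).
#' @return Character vector of selected marker names (possibly empty).
#' @export
vip_filter <- function(vip_scores, threshold = 1.0) {
  if (any(!is.finite(vip_scores))) stop("VIP scores must be finite")
  sel <- vip_scores[vip_scores > threshold]
  names(sort(sel, decreasing = TRUE))
}

#' Intersect marker panels
#'
#' Set intersection of two or more marker panels (e.g. the VIP > 1 panels of
#' several PLS-DA models), retaining the provenance of each input panel.
#'
#' @param panels List (>= 2) of character vectors of marker names; no panel
#'   may be empty.
#' @return Object of class `marker_panel`: `selected` (the intersection,
#'   in the order of the first panel) and `provenance` (the input panels).
#'   Warns when the intersection is empty.
#' @export
shared_markers <- function(panels) {
  if (!is.list(panels) || length(panels) < 2)
    stop("need a list of >= 2 panels")
  if (any(lengths(panels) == 0)) stop("empty panel input")
  common <- Reduce(intersect, panels)
  if (length(common) == 0) warning("no shared markers across panels")
  if (is.null(names(panels)))
    names(panels) <- paste0("panel", seq_along(panels))
  structure(list(selected = common, provenance = panels),
            class = "marker_panel")
}

#' One-way ANOVA with Duncan's multiple range test letters
#'
#' Runs a one-way ANOVA across groups, then Duncan's stepwise multiple range
#' test at level `alpha` on the rank-ordered group means using the pooled
#' mean-square error: the critical range for a span of k ordered means uses
#' the studentized-range quantile at the protected level
#' `1 - (1 - alpha)^(k - 1)`. Groups are labelled with a compact letter
#' display ("a" = highest mean); groups sharing a letter are not
#' significantly different.
#'
#' @param values Named list of numeric vectors (one per group, each n >= 2),
#'   or a data.frame with columns `value` and `group`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `duncan_result`: `table` (data.frame with group,
#'   n, mean, sd, letters, ordered by decreasing mean), `F`, `p_value`,
#'   `MSE`, `df_error`, `alpha`.
#' @export
#' @examples
#' g <- list(a = c(10, 11, 10.5), b = c(5, 5.2, 4.9), c = c(5.1, 5.0, 5.2))
#' anova_duncan(g)$table
anova_duncan <- function(values, alpha = 0.05) {
  if (is.data.frame(values)) {
    values <- split(values$value, values$group)
  }
  if (length(values) < 2) stop("need >= 2 groups")
  if (any(lengths(values) < 2)) stop("each group needs n >= 2")
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  y <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))
  if (all(vapply(values, stats::var, 0) == 0))
    stop("zero within-group variance in every group; Duncan test undefined")
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  means <- vapply(values, mean, 0)
  ns <- lengths(values)
  nh <- length(ns) / sum(1 / ns)          # harmonic mean group size
  ord <- order(means, decreasing = TRUE)
  ms <- means[ord]
  k <- length(ms)
  # critical range per span, protected significance levels
  crit <- vapply(2:k, function(span) {
    p <- (1 - alpha)^(span - 1)
    stats::qtukey(p, span, dfe) * sqrt(mse / nh)
  }, 0)
  # interval [i, j] (sorted order) not significant if some containing
  # interval has range <= its critical value (Duncan's protection rule)
  ok <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i)
    ok[i, j] <- (ms[i] - ms[j]) <= crit[j - i]
  nonsig <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) { nonsig[i, j] <- TRUE; next }
    cover <- FALSE
    for (a in 1:i) for (b in j:k) if (ok[a, b]) cover <- TRUE
    nonsig[i, j] <- cover
  }
  # maximal nonsignificant intervals -> letters
  jmax <- vapply(seq_len(k), function(i) max(which(nonsig[i, i:k]) + i - 1L), 0L)
  intervals <- unique(data.frame(from = seq_len(k), to = jmax))
  keep <- !vapply(seq_len(nrow(intervals)), function(r) {
    any(intervals$from < intervals$from[r] & intervals$to >= intervals$to[r])
  }, logical(1))
  intervals <- intervals[keep, , drop = FALSE]
  letters_per_group <- character(k)
  for (r in seq_len(nrow(intervals))) {
    span <- intervals$from[r]:intervals$to[r]
    letters_per_group[span] <- paste0(letters_per_group[span], letters[r])
  }
  tab <- data.frame(group = names(ms), n = ns[ord], mean = ms,
                    sd = vapply(values, stats::sd, 0)[ord],
                    letters = letters_per_group, row.names = NULL)
  structure(list(table = tab, F = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1], MSE = mse, df_error = dfe,
                 alpha = alpha),
            class = "duncan_result")
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g (MSE %.4g, df %d)\n",
              x$F, x$p_value, x$MSE, x$df_error))
  cat(sprintf("Duncan's multiple range test letters (alpha = %g):\n", x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Marker x species summary table with significance letters
#'
#' Builds a table shaped like a means +/- SD compendium: one row per marker,
#' one column per species, each cell "mean +/- SD^letters^" from
#' [anova_duncan] on that marker.
#'
#' @param concentrations Samples x markers matrix.
#' @param labels Species label per sample.
#' @param alpha Significance level (default 0.05).
#' @param units Optional per-marker unit strings appended to the row names.
#' @return data.frame, markers x species.
#' @export
marker_letter_table <- function(concentrations, labels, alpha = 0.05,
                                units = NULL) {
  labels <- factor(labels)
  out <- NULL
  for (j in seq_len(ncol(concentrations))) {
    res <- anova_duncan(split(concentrations[, j], labels), alpha = alpha)
    tb <- res$table[match(levels(labels), res$table$group), ]
    cells <- sprintf("%.2f ± %.2f^%s^", tb$mean, tb$sd, tb$letters)
    out <- rbind(out, cells)
  }
  nm <- colnames(concentrations)
  if (!is.null(units)) nm <- paste0(nm, " (", units, ")")
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  dimnames(out) <- list(nm, levels(labels))
  out
}
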