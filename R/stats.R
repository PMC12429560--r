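#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction and chi-square reference
#' distribution (via [stats::kruskal.test()]). All-identical observations
#' give H = 0, p = 1.
#'
#' @param groups List of numeric vectors (>= 2 non-empty groups).
#' @return `list(H, p)`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) return(list(H = 0, p = 1))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

# internal: Mann-Whitney U with tie-corrected normal Z.
# U is the number of (x, y) pairs with x > y (+ half the ties), i.e. the
# statistic of the first sample. Z uses the tie-corrected variance and no
# continuity correction (it feeds Cohen's r); the p-value is exact (via
# the null distribution of U) for combined n <= exact_max without ties,
# otherwise a tie- and continuity-corrected normal approximation.
mann_whitney_core <- function(x, y, exact_max = 20L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  has_ties <- any(ties > 1)
  if (n1 == 1 && n2 == 1) {
    p <- 1; method <- "degenerate"
  } else if (!has_ties && n <= exact_max) {
    p <- wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else if (sigma2 == 0) {
    p <- 1; method <- "normal"
  } else {
    zc <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(zc)))
    method <- "normal"
  }
  list(U = U, p = p, Z = z, n1 = n1, n2 = n2, method = method)
}

#' Cohen's r effect size for a Mann-Whitney comparison
#'
#' Computes \eqn{r = |Z| / \sqrt{n_1 + n_2}} with Z from the tie-corrected normal
#' approximation of U (no continuity correction), so r = 0 when U sits at
#' its null mean `n1 n2 / 2`.
#'
#' @param U Mann-Whitney U statistic of the first sample.
#' @param n1,n2 Group sizes.
#' @param tie_structure Optional vector of tied-group sizes in the
#'   combined sample (e.g. `c(2, 3)` for one pair and one triple); omit
#'   when there are no ties.
#' @return Cohen's r in \[0, 1\].
#' @export
cohens_r <- function(U, n1, n2, tie_structure = NULL) {
  n <- n1 + n2
  tie_term <- if (is.null(tie_structure)) 0
              else sum(tie_structure^3 - tie_structure) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  abs(U - n1 * n2 / 2) / sqrt(sigma2) / sqrt(n)
}

#' Bin an effect size at the conventional thresholds
#'
#' Thresholds r = 0.1 (small), 0.3 (medium), 0.5 (large); below 0.1 is
#' negligible.
#'
#' @param r Cohen's r value(s).
#' @return Factor with levels negligible/small/medium/large.
#' @export
effect_bin <- function(r) {
  cut(r, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large"))
}

#' Pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney U for every pair of groups, with the adjusted
#' significance threshold `alpha / family_size` (family size 10 gives the
#' 0.005 threshold, family size 3 gives 0.0167). P-values are exact for
#' combined n <= 20 without ties, otherwise a tie- and
#' continuity-corrected normal approximation. Cohen's r accompanies each
#' comparison; degenerate 1-vs-1 comparisons get p = 1 and are flagged.
#'
#' @param groups Named list of numeric vectors.
#' @param family_size Number of tests in the Bonferroni family; must be at
#'   least the number of pairwise comparisons (default: exactly that).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame of `StatSummary` rows: comparison, U, Z, p_raw,
#'   alpha_adjusted, significant, r, effect_bin, degenerate.
#' @export
mann_whitney_pairwise <- function(groups, family_size = NULL, alpha = 0.05) {
  k <- length(groups)
  if (k < 2 || any(lengths(groups) == 0))
    stop("need >= 2 non-empty groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  if (is.null(family_size)) family_size <- ncol(pairs)
  if (family_size < ncol(pairs))
    stop("family_size must be >= the number of comparisons")
  alpha_adj <- alpha / family_size
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    mw <- mann_whitney_core(groups[[a]], groups[[b]])
    r <- abs(mw$Z) / sqrt(mw$n1 + mw$n2)
    out[[j]] <- data.frame(
      comparison = paste(names(groups)[a], "vs", names(groups)[b]),
      U = mw$U, Z = mw$Z, p_raw = mw$p, alpha_adjusted = alpha_adj,
      significant = mw$p < alpha_adj, r = r,
      effect_bin = as.character(effect_bin(r)),
      degenerate = mw$method == "degenerate", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Genotype comparison statistics for a cohort
#'
#' For each (molecule, age, segment), compares WT and Q175KI samples with
#' Kruskal-Wallis followed by the pairwise Mann-Whitney U test at the
#' Bonferroni-adjusted threshold, on either per-sample compartment
#' intensities or per-sample ISMP values.
#'
#' @param values Data frame with a `value` column and grouping columns
#'   molecule, age, segment, genotype (e.g. densitometry records filtered
#'   to one compartment and renamed, or [compute_ISMP()] output with
#'   `value = ISMP`).
#' @param family_size Bonferroni family size (default 10, the convention
#'   behind the p < 0.005 threshold).
#' @return Data frame with one row per (molecule, age, segment): H, U, Z,
#'   p_raw, alpha_adjusted, significant, r, effect_bin.
#' @export
genotype_stats <- function(values, family_size = 10L) {
  stopifnot(all(c("molecule", "age", "segment", "genotype", "value") %in%
                  names(values)))
  keys <- unique(values[c("molecule", "age", "segment")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- values$molecule == keys$molecule[i] & values$age == keys$age[i] &
      values$segment == keys$segment[i]
    wt <- values$value[sel & values$genotype == "WT"]
    ki <- values$value[sel & values$genotype == "Q175KI"]
    if (length(wt) == 0 || length(ki) == 0) next
    kw <- kruskal_wallis(list(WT = wt, Q175KI = ki))
    mw <- mann_whitney_pairwise(list(WT = wt, Q175KI = ki),
                                family_size = family_size)
    out[[length(out) + 1]] <- cbind(keys[i, , drop = FALSE],
                                    data.frame(H = kw$H), mw,
                                    row.names = NULL)
  }
  do.call(rbind, out)
}

#' Heatmap-style report tables of RI and effect sizes
#'
#' Builds the two report matrices (molecule by segment-and-age): relative
#' intensity with significance markers, and Cohen's r, plus per-molecule
#' ISMP group summaries. Cells absent from the inputs are explicit NA.
#' Optionally writes `heatmap_RI.csv`, `heatmap_effect.csv` and
#' `ismp_summary.csv` (and, when the pheatmap package is available,
#' rendered PNG heatmaps) into `out_dir`.
#'
#' @param ri [compute_RI()] output filtered to one compartment (or with a
#'   `compartment` column, filtered by `compartment`).
#' @param ismp_summary [summarize_ISMP()] output.
#' @param stats [genotype_stats()] output aligned on
#'   (molecule, age, segment).
#' @param compartment Compartment reported in the RI matrix.
#' @param out_dir Optional output directory.
#' @return List with matrices `RI`, `effect`, significance matrix
#'   `significant`, marker matrix `marked` (RI with `*`), and the
#'   `ismp_summary` data frame.
#' @export
heatmap_tables <- function(ri, ismp_summary, stats,
                           compartment = "striosome", out_dir = NULL) {
  if ("compartment" %in% names(ri)) ri <- ri[ri$compartment == compartment, ]
  mols <- striatal_molecules()
  segs <- c("WH", segment_names())
  ages <- sort(unique(ri$age))
  cols <- as.vector(outer(segs, ages, function(s, a) paste0(s, "_", a, "mo")))
  mk <- function() matrix(NA_real_, length(mols), length(cols),
                          dimnames = list(mols, cols))
  RI <- mk(); eff <- mk(); sig <- mk()
  for (i in seq_len(nrow(ri))) {
    cn <- paste0(ri$segment[i], "_", ri$age[i], "mo")
    if (ri$molecule[i] %in% mols && cn %in% cols)
      RI[ri$molecule[i], cn] <- ri$RI[i]
  }
  for (i in seq_len(nrow(stats))) {
    cn <- paste0(stats$segment[i], "_", stats$age[i], "mo")
    if (stats$molecule[i] %in% mols && cn %in% cols) {
      eff[stats$molecule[i], cn] <- stats$r[i]
      sig[stats$molecule[i], cn] <- as.numeric(stats$significant[i])
    }
  }
  marked <- matrix(ifelse(is.na(RI), "NA",
                          paste0(formatC(RI, digits = 3, format = "f"),
                                 ifelse(!is.na(sig) & sig == 1, " *", ""))),
                   nrow(RI), ncol(RI), dimnames = dimnames(RI))
  out <- list(RI = RI, effect = eff, significant = sig, marked = marked,
              ismp_summary = ismp_summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(RI, file.path(out_dir, "heatmap_RI.csv"))
    write.csv(eff, file.path(out_dir, "heatmap_effect.csv"))
    write.csv(ismp_summary, file.path(out_dir, "ismp_summary.csv"),
              row.names = FALSE)
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      for (nm in c("RI", "effect")) {
        m <- out[[nm]]
        m[is.na(m)] <- 0
        # a constant matrix cannot be colour-scaled; skip the figure then
        tryCatch({
          grDevices::png(file.path(out_dir, paste0("heatmap_", nm, ".png")),
                         width = 1200, height = 500, res = 120)
          pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                             display_numbers =
                               if (nm == "RI") marked else TRUE,
                             main = if (nm == "RI")
                               "Relative intensity (Q175KI / WT)"
                             else "Effect size (Cohen's r)")
        }, error = function(e) NULL, finally = grDevices::dev.off())
      }
    }
  }
  out
}
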