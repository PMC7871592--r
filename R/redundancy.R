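# Group comparisons and the cross-metric redundancy analysis: bivariate
# correlations (Spearman; circular variants for angle-valued metrics) and
# a consensus matrix over the three inter-regional connections.

#' Bivariate correlations between metric columns
#'
#' Spearman's rho for linear-linear pairs; Jammalamadaka-SenGupta
#' circular-circular and Mardia circular-linear correlation for
#' angle-valued metrics (degrees). P-values are reported unadjusted.
#'
#' @param table data.frame of per-observation metric values.
#' @param circular character vector naming angle-valued columns.
#' @param metrics columns to correlate (default all numeric).
#' @return data.frame: metric_a, metric_b, rho, p, n, method.
#' @export
correlate_metrics <- function(table, circular = character(0),
                              metrics = NULL) {
  if (is.null(metrics))
    metrics <- names(table)[vapply(table, is.numeric, logical(1))]
  out <- NULL
  for (i in seq_along(metrics)) for (j in seq_along(metrics)) {
    if (j <= i) next
    a <- metrics[i]; b <- metrics[j]
    ok <- stats::complete.cases(table[[a]], table[[b]])
    xa <- table[[a]][ok]; xb <- table[[b]][ok]
    n <- length(xa)
    if (n < 3) next
    ca <- a %in% circular; cb <- b %in% circular
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
      res <- list(rho = NA_real_, p = NA_real_)
      method <- "undefined"
    } else if (ca && cb) {
      res <- circ_circ_cor(deg2rad(xa), deg2rad(xb))
      method <- "circ_circ"
    } else if (ca || cb) {
      th <- if (ca) deg2rad(xa) else deg2rad(xb)
      lin <- if (ca) xb else xa
      res <- circ_lin_cor(th, lin)
      method <- "circ_lin"
    } else {
      ct <- suppressWarnings(
        stats::cor.test(xa, xb, method = "spearman"))
      res <- list(rho = unname(ct$estimate), p = ct$p.value)
      method <- "spearman"
    }
    out <- rbind(out, data.frame(metric_a = a, metric_b = b,
                                 rho = res$rho, p = res$p, n = n,
                                 method = method))
  }
  out
}

#' Consensus matrix across connections
#'
#' For each metric pair: the mean correlation over the connections, with a
#' significance flag set only when the pair is significant in every
#' connection (flags at alpha 0.01 and 0.001). Pairs missing from any
#' connection are dropped with a warning.
#'
#' @param cells data.frame from [correlate_metrics()] with an added
#'   `connection` column (or a named list of per-connection tables).
#' @param alphas significance levels for the flags.
#' @return data.frame: metric_a, metric_b, mean_rho, n_connections,
#'   plus one logical `sig_<alpha>` column per alpha.
#' @export
consensus <- function(cells, alphas = c(0.01, 0.001)) {
  if (is.list(cells) && !is.data.frame(cells)) {
    cells <- do.call(rbind, lapply(names(cells), function(cn)
      cbind(cells[[cn]], connection = cn)))
  }
  n_conn <- length(unique(cells$connection))
  key <- paste(cells$metric_a, cells$metric_b, sep = "|")
  out <- NULL
  for (k in unique(key)) {
    sub <- cells[key == k, ]
    if (nrow(sub) < n_conn) {
      warning("metric pair ", k, " missing in some connection; dropped")
      next
    }
    row <- data.frame(metric_a = sub$metric_a[1], metric_b = sub$metric_b[1],
                      mean_rho = mean(sub$rho), n_connections = nrow(sub))
    for (a in alphas)
      row[[sprintf("sig_%g", a)]] <- all(is.finite(sub$p)) && all(sub$p < a)
    out <- rbind(out, row)
  }
  out
}

#' Group comparison dispatch
#'
#' Linear metrics: Welch two-sample t test. Circular metrics (angles in
#' degrees): Watson-Williams. Paired-direction designs (e.g. the two
#' directions of a GC connection per subject): two-factor mixed ANOVA
#' (group x within-condition, subject as error stratum) with
#' Sidak-adjusted pairwise group contrasts per condition.
#'
#' @param values numeric vector of metric values (for "linear"/"circular"),
#'   or a data.frame with columns `value`, `group`, `subject`, `condition`
#'   for "paired_directions".
#' @param group group labels (two levels) for the vector forms.
#' @param kind "linear", "circular", or "paired_directions".
#' @return a `group_comparison`: `test`, `statistic`, `p`, `means`,
#'   `sem`, and for the ANOVA path `contrasts` (Sidak-adjusted).
#' @export
compare_groups <- function(values, group = NULL,
                           kind = c("linear", "circular",
                                    "paired_directions")) {
  kind <- match.arg(kind)
  if (kind %in% c("linear", "circular")) {
    group <- as.factor(group)
    if (nlevels(group) != 2) stop("need exactly two groups")
    if (any(table(group) < 2)) stop("need >= 2 observations per group")
    sp <- split(values, group)
    if (kind == "linear") {
      tt <- stats::t.test(sp[[1]], sp[[2]])  # Welch
      res <- list(test = "welch_t", statistic = unname(tt$statistic),
                  p = tt$p.value,
                  means = vapply(sp, mean, numeric(1)),
                  sem = vapply(sp, function(v) stats::sd(v) / sqrt(length(v)),
                               numeric(1)))
    } else {
      ww <- watson_williams(deg2rad(sp[[1]]), deg2rad(sp[[2]]))
      res <- list(test = "watson_williams", statistic = ww$F, p = ww$p,
                  means = vapply(sp, function(v)
                    rad2deg(circ_resultant(deg2rad(v))$mu) %% 360,
                    numeric(1)),
                  sem = c(NA_real_, NA_real_))
    }
    return(structure(res, class = "group_comparison"))
  }
  df <- values
  stopifnot(all(c("value", "group", "subject", "condition") %in% names(df)))
  df$group <- as.factor(df$group); df$condition <- as.factor(df$condition)
  df$subject <- as.factor(df$subject)
  fit <- stats::aov(value ~ group * condition + Error(subject / condition),
                    data = df)
  sm <- summary(fit)
  # pull group, condition and interaction p-values from the two strata
  tab_b <- sm[["Error: subject"]][[1]]
  tab_w <- sm[["Error: subject:condition"]][[1]]
  p_group <- tab_b["group", "Pr(>F)"]
  p_cond <- tab_w["condition", "Pr(>F)"]
  p_int <- tab_w["group:condition", "Pr(>F)"]
  contrasts <- NULL
  if ((is.finite(p_group) && p_group < 0.05) ||
      (is.finite(p_int) && p_int < 0.05)) {
    conds <- levels(df$condition)
    m <- length(conds)
    contrasts <- do.call(rbind, lapply(conds, function(cc) {
      sub <- df[df$condition == cc, ]
      sp <- split(sub$value, sub$group)
      tt <- stats::t.test(sp[[1]], sp[[2]])
      data.frame(condition = cc, p_raw = tt$p.value,
                 p_sidak = 1 - (1 - tt$p.value)^m)
    }))
  }
  structure(list(test = "mixed_anova_sidak",
                 statistic = c(F_group = tab_b["group", "F value"],
                               F_condition = tab_w["condition", "F value"],
                               F_interaction = tab_w["group:condition", "F value"]),
                 p = c(group = p_group, condition = p_cond,
                       interaction = p_int),
                 means = tapply(df$value, list(df$group, df$condition), mean),
                 sem = NULL, contrasts = contrasts),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$test))
  if (length(x$p) == 1)
    cat(sprintf("  statistic %.3f, p = %.4g\n", x$statistic, x$p))
  else
    for (nm in names(x$p))
      cat(sprintf("  %s: p = %.4g\n", nm, x$p[nm]))
  invisible(x)
}
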