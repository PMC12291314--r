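# Comparative statistics: the range-based variability statistic V and its
# between-variety difference, one-way ANOVA with Fisher-LSD compact letter
# displays, balanced two-way ANOVA star tables, relative-to-control JIP
# profiles, and starred Pearson correlation matrices.

#' Range-based variability statistic
#'
#' `V = (max - min) / max` over the treatment-group means of a trait,
#' computed per variety (replicates are averaged first; the statistic is
#' only reproducible on means). `delta_V = |V_a - V_b|` for the configured
#' variety pair. V is scale-invariant and lies in `[0, 1)` for positive
#' means.
#'
#' @param table a [group_table()].
#' @param trait trait name to analyse.
#' @param varieties length-2 character vector naming the pair for
#'   `delta_V`; defaults to the first two varieties present.
#' @return list of class `variability_result` with fields `trait`,
#'   `V_per_variety` (named numeric) and `delta_V`.
#' @export
variability <- function(table, trait, varieties = NULL) {
  table <- group_table(table)
  sub <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("trait '%s' not present in table", trait))
  means <- tapply(sub$value, list(sub$variety, sub$treatment), mean)
  V <- apply(means, 1L, variability_stat)
  if (is.null(varieties)) varieties <- utils::head(names(V), 2L)
  dV <- if (length(varieties) == 2L && all(varieties %in% names(V)))
    abs(V[[varieties[1L]]] - V[[varieties[2L]]]) else NA_real_
  structure(list(trait = trait, V_per_variety = V, delta_V = dV),
            class = "variability_result")
}

#' The V statistic on a vector of group means
#'
#' @param means numeric vector of treatment means (at least 2; max > 0).
#' @return `(max - min)/max`.
#' @export
variability_stat <- function(means) {
  means <- means[!is.na(means)]
  if (length(means) < 2L) stop("variability needs >= 2 treatment means")
  mx <- max(means)
  if (mx <= 0) stop("domain error: max of means must be > 0")
  (mx - min(means)) / mx
}

# ---------------------------------------------------------------------------
# Compact letter display by insert-and-absorb.
# `distinct` is a symmetric logical matrix: TRUE where the pair is
# significantly different. Groups must be ordered by decreasing mean so
# that letter "a" lands on the largest mean. Returns a character vector of
# letter strings, one per group, satisfying the biconditional: two groups
# share a letter iff they are NOT significantly different.
cld_insert_absorb <- function(distinct) {
  k <- nrow(distinct)
  cols <- list(rep(TRUE, k))  # one letter covering everybody
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    if (!distinct[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci == cj || !keep[ci]) next
      if (all(cols[[ci]] <= cols[[cj]]) && keep[cj] &&
          !identical(cols[[ci]], cols[[cj]])) keep[ci] <- FALSE
      else if (identical(cols[[ci]], cols[[cj]]) && ci > cj) keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  # order letters so "a" goes with the highest-mean (first) groups
  ord <- order(vapply(cols, function(col) which(col)[1L], 0L))
  cols <- cols[ord]
  letters_used <- letters[seq_along(cols)]
  vapply(seq_len(k), function(g)
    paste(letters_used[vapply(cols, function(col) col[g], TRUE)],
          collapse = ""), "")
}

#' One-way ANOVA with Fisher-LSD letter groups
#'
#' Classic unadjusted Fisher LSD: a one-way fixed-effects ANOVA supplies
#' the pooled error mean square (MSE) and its degrees of freedom; every
#' pair of groups is then compared with an LSD t-test,
#' `|m_i - m_j| > t(1 - alpha/2, df) * sqrt(MSE (1/n_i + 1/n_j))`, and the
#' significance pattern is condensed into a compact letter display by
#' insert-and-absorb, letter "a" on the largest mean. When the within-group
#' variance is exactly zero everywhere, any difference in means counts as
#' significant.
#'
#' @param table a [group_table()].
#' @param trait trait name to analyse.
#' @param grouping grouping column, `"treatment"` (default) or `"variety"`.
#' @param alpha significance level for the letter display.
#' @param variety optional variety label to subset to first (letters within
#'   one variety across treatments, as in a time-course table).
#' @param levels optional explicit order of group labels (display order;
#'   letters themselves depend only on means).
#' @return data.frame of class `anova_letters` with columns `group`,
#'   `mean`, `sd`, `n`, `letters`, plus attributes `F`, `p`, `df`, `MSE`,
#'   `alpha`, `trait`.
#' @export
one_way_anova_lsd <- function(table, trait, grouping = "treatment",
                              alpha = 0.05, variety = NULL, levels = NULL) {
  table <- group_table(table)
  sub <- table[table$trait == trait, , drop = FALSE]
  if (!is.null(variety)) sub <- sub[sub$variety == variety, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("trait '%s' not present in table", trait))
  g <- sub[[grouping]]
  labs <- if (is.null(levels)) unique(g) else levels
  vals <- split(sub$value, factor(g, levels = labs))
  n <- vapply(vals, length, 0L)
  if (length(vals) < 2L) stop("usage error: need >= 2 groups")
  if (any(n < 2L))
    stop(sprintf("usage error: group '%s' has n < 2", labs[which(n < 2L)[1L]]))
  m <- vapply(vals, mean, 0)
  s <- vapply(vals, stats::sd, 0)
  N <- sum(n); k <- length(vals)
  sse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0))
  ssb <- sum(n * (m - mean(sub$value))^2)
  df_err <- N - k
  mse <- sse / df_err
  Fstat <- if (mse > 0) (ssb / (k - 1)) / mse else Inf
  pval <- if (mse > 0) stats::pf(Fstat, k - 1, df_err, lower.tail = FALSE) else 0
  # pairwise LSD decisions
  distinct <- matrix(FALSE, k, k)
  tcrit <- stats::qt(1 - alpha / 2, df_err)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    d <- abs(m[i] - m[j])
    distinct[i, j] <- distinct[j, i] <-
      if (mse == 0) d > 0 else d > tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
  }
  ord <- order(m, decreasing = TRUE)
  lets <- character(k)
  lets[ord] <- cld_insert_absorb(distinct[ord, ord, drop = FALSE])
  out <- data.frame(group = labs, mean = unname(m), sd = unname(s),
                    n = unname(n), letters = lets, stringsAsFactors = FALSE)
  structure(out, class = c("anova_letters", "data.frame"),
            F = Fstat, p = pval, df = c(k - 1, df_err), MSE = mse,
            alpha = alpha, trait = trait)
}

#' Balanced two-way ANOVA star table
#'
#' Fixed-effects two-way ANOVA with interaction on a balanced (full
#' factorial, equal replication not required but every cell needs n >= 2)
#' layout; sequential (type-I) sums of squares, which coincide with all
#' other types on balanced data. Each effect's p-value is mapped to the
#' conventional stars: `"**"` for p < 0.01, `"*"` for p < 0.05, `"NS"`
#' otherwise.
#'
#' @param table a [group_table()].
#' @param trait trait name.
#' @param factors length-2 character vector of grouping columns, default
#'   `c("variety", "treatment")`.
#' @return data.frame of class `anova_stars` with columns `effect`, `df`,
#'   `SS`, `F`, `p`, `stars` (rows: the two main effects, the interaction,
#'   and `Residuals`), plus attribute `SS_total`.
#' @export
two_way_anova <- function(table, trait, factors = c("variety", "treatment")) {
  table <- group_table(table)
  sub <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("trait '%s' not present in table", trait))
  A <- factor(sub[[factors[1L]]])
  B <- factor(sub[[factors[2L]]])
  tab <- base::table(A, B)
  if (any(tab == 0)) stop("usage error: missing factorial cell(s)")
  if (any(tab < 2)) stop("usage error: every cell needs replication (n >= 2)")
  fit <- stats::aov(sub$value ~ A * B)
  an <- stats::anova(fit)
  eff <- c(factors[1L], factors[2L],
           paste(factors[1L], factors[2L], sep = " x "), "Residuals")
  p <- an[["Pr(>F)"]]
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
  out <- data.frame(effect = eff, df = an$Df, SS = an[["Sum Sq"]],
                    F = an[["F value"]], p = p, stars = stars,
                    stringsAsFactors = FALSE)
  structure(out, class = c("anova_stars", "data.frame"),
            SS_total = sum((sub$value - mean(sub$value))^2), trait = trait)
}

#' Relative-to-control trait profiles
#'
#' Divides every trait's treatment-group mean by the same variety's control
#' mean, so the control row maps to exactly 1 and the other rows express
#' the relative change (e.g. 1.18 for +18%). The standard display for JIP
#' parameter panels.
#'
#' @param table a [group_table()] (typically from [jip_parameter_table()]).
#' @param control_label treatment label of the control group.
#' @return A [group_table()] of mean ratios, one row per
#'   (variety, treatment, trait), with `replicate = 1`.
#' @export
relative_profile <- function(table, control_label = "0h") {
  table <- group_table(table)
  if (!control_label %in% table$treatment)
    stop(sprintf("control treatment '%s' not present", control_label))
  agg <- stats::aggregate(value ~ variety + treatment + trait, data = table,
                          FUN = mean)
  ctl <- agg[agg$treatment == control_label, c("variety", "trait", "value")]
  names(ctl)[3L] <- "control_mean"
  merged <- merge(agg, ctl, by = c("variety", "trait"), sort = FALSE)
  if (any(merged$control_mean == 0))
    stop_singular("zero control mean in relative profile")
  merged$value <- merged$value / merged$control_mean
  group_table(data.frame(variety = merged$variety, treatment = merged$treatment,
                         replicate = 1L, trait = merged$trait,
                         value = merged$value, stringsAsFactors = FALSE))
}

#' Significance stars for p-values (correlation convention)
#'
#' `"***"` p < 0.001, `"**"` p < 0.01, `"*"` p < 0.05, `"·"` p < 0.10,
#' `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of stars.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*",
          ifelse(p < 0.10, "·", "")))))
}

#' Starred Pearson correlation matrix across traits
#'
#' Reshapes a tidy trait table to one observation per
#' (variety, treatment, replicate) and computes pairwise-complete Pearson
#' correlations with two-sided p-values for every trait pair. By default
#' observations are pooled across varieties and treatments; with
#' `by_variety = TRUE` a separate matrix is returned per variety (trait
#' relationships can differ between tolerant and sensitive material).
#'
#' @param table a [group_table()].
#' @param traits character vector of traits to include (default: all).
#' @param by_variety compute one matrix per variety instead of pooling.
#' @return An object of class `trait_correlation`: list with `traits`, `r`,
#'   `p`, `n`, `stars` (symmetric matrices; unit diagonal on `r`, empty
#'   diagonal stars - the diagonal is not a test). With
#'   `by_variety = TRUE`, a named list of such objects.
#' @export
correlation_matrix <- function(table, traits = NULL, by_variety = FALSE) {
  table <- group_table(table)
  if (is.null(traits)) traits <- unique(table$trait)
  if (by_variety) {
    vs <- unique(table$variety)
    out <- lapply(vs, function(v)
      correlation_matrix(table[table$variety == v, , drop = FALSE], traits))
    names(out) <- vs
    return(out)
  }
  k <- length(traits)
  obs_key <- function(df) paste(df$variety, df$treatment, df$replicate, sep = "\r")
  keys <- sort(unique(obs_key(table)))
  wide <- matrix(NA_real_, length(keys), k, dimnames = list(keys, traits))
  for (tr in traits) {
    sub <- table[table$trait == tr, , drop = FALSE]
    wide[obs_key(sub), tr] <- sub$value
  }
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1
  warned <- character(0)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    x <- wide[, i]; y <- wide[, j]
    ok <- stats::complete.cases(x, y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warned <- union(warned, traits[c(i, j)[c(stats::sd(x[ok]) == 0,
                                               stats::sd(y[ok]) == 0)]])
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (length(warned))
    warning(sprintf("constant trait(s) %s: correlations undefined, set to NA",
                    paste(warned, collapse = ", ")))
  stars <- matrix(p_stars(p), k, k, dimnames = list(traits, traits))
  diag(stars) <- ""
  structure(list(traits = traits, r = r, p = p, n = nmat, stars = stars),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, digits = 2, ...) {
  cat(sprintf("<trait_correlation> %d traits\n", length(x$traits)))
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                 length(x$traits), length(x$traits),
                 dimnames = list(x$traits, x$traits))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Tidy export of a correlation matrix
#'
#' @param x a `trait_correlation`.
#' @return data.frame with columns trait_i, trait_j, r, p, n, stars (upper
#'   triangle only).
#' @export
correlation_table <- function(x) {
  stopifnot(inherits(x, "trait_correlation"))
  k <- length(x$traits)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  data.frame(trait_i = x$traits[idx[, 1L]], trait_j = x$traits[idx[, 2L]],
             r = x$r[idx], p = x$p[idx], n = x$n[idx], stars = x$stars[idx],
             stringsAsFactors = FALSE)
}
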