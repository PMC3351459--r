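#' Replicate-noise standard deviation for one gene and condition
#'
#' The noise model perturbs log2 condition means with Gaussian noise of
#' standard deviation \code{s / sqrt(n)}, where \code{s} is the sample
#' standard deviation of the \code{n} log2 replicate values: dividing by
#' \code{sqrt(n)} is the shortcut for averaging \code{n} independent
#' Gaussian draws of standard deviation \code{s}.
#'
#' @param matrix an \code{expression_matrix}.
#' @param gene gene id.
#' @param condition condition label.
#' @return the log2-scale standard deviation; with a single replicate the
#'   median of all computable per-(gene, condition) values is returned
#'   instead, with a message.
#' @export
estimate_noise_sd <- function(matrix, gene, condition) {
  stopifnot(inherits(matrix, "expression_matrix"))
  sds <- noise_sd_matrix(matrix, fill = FALSE)
  if (!gene %in% rownames(sds)) stop("unknown gene '", gene, "'", call. = FALSE)
  if (!condition %in% colnames(sds))
    stop("unknown condition '", condition, "'", call. = FALSE)
  v <- sds[gene, condition]
  if (is.na(v)) {
    v <- stats::median(sds, na.rm = TRUE)
    message("condition '", condition, "' has a single replicate for '", gene,
            "'; using the median of computable sds (", format(v), ")")
  }
  v
}

# gene x condition matrix of sd(log2 replicates)/sqrt(n); NA where n < 2,
# then filled with the overall median when any column is computable
noise_sd_matrix <- function(matrix, fill = TRUE) {
  lv <- log2(pmax(matrix$values, .Machine$double.xmin))
  conds <- unique(unname(matrix$conditions))
  out <- matrix(NA_real_, nrow(lv), length(conds),
                dimnames = list(rownames(lv), conds))
  for (cc in conds) {
    cols <- which(matrix$conditions == cc)
    if (length(cols) < 2L) next
    out[, cc] <- apply(lv[, cols, drop = FALSE], 1, stats::sd) /
      sqrt(length(cols))
  }
  if (fill && anyNA(out) && !all(is.na(out)))
    out[is.na(out)] <- stats::median(out, na.rm = TRUE)
  out
}

#' Stochastic (replicate-noise) robustness analysis
#'
#' Repeatedly perturbs the log2 condition means with gene- and
#' condition-specific Gaussian noise (standard deviation from
#' [estimate_noise_sd()]), exponentiates back, recomputes
#' expression-derived ratios and the candidate ranking for every challenge
#' condition, and summarizes the distribution of the matching candidate's
#' tie-averaged rank.
#'
#' @param model a \code{metabolic_model}.
#' @param baseline a \code{baseline_limits}.
#' @param matrix replicate-level \code{expression_matrix} (source of both
#'   the means and the noise scale).
#' @param iterations number of noise draws; default 1000.
#' @param seed integer seed for reproducibility.
#' @param conditions challenge conditions to analyze; default every
#'   condition whose label names a candidate.
#' @param sigma_scale global multiplier on the noise sd (1 = as estimated).
#' @param floor_epsilon optional minimum upper flux limit after scaling.
#' @return object of class \code{rank_distribution_set}: per-condition list
#'   with \code{ranks} (per-iteration matching rank), \code{mean},
#'   \code{sd}.
#' @export
stochastic_analysis <- function(model, baseline, matrix, iterations = 1000,
                                seed = NULL, conditions = NULL,
                                sigma_scale = 1, floor_epsilon = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!is.null(seed)) set.seed(seed)
  expr0 <- condition_means(matrix, floor_value = .Machine$double.xmin)
  if (is.null(conditions))
    conditions <- intersect(expr0$conditions, names(baseline$per_nutrient))
  if (length(conditions) == 0L)
    stop("no challenge condition names a candidate nutrient", call. = FALSE)
  sds <- noise_sd_matrix(matrix)[, expr0$conditions, drop = FALSE] * sigma_scale
  lmeans <- log2(pmax(expr0$means, .Machine$double.xmin))

  ranks <- matrix(NA_real_, iterations, length(conditions),
                  dimnames = list(NULL, conditions))
  for (it in seq_len(iterations)) {
    noise <- stats::rnorm(length(lmeans), sd = pmax(sds, 0))
    perturbed <- 2^(lmeans + matrix(noise, nrow(lmeans), ncol(lmeans)))
    expr <- expression_set(perturbed)
    for (cc in conditions) {
      res <- prioritize(model, baseline, expr, cc, matching = cc,
                        floor_epsilon = floor_epsilon)
      ranks[it, cc] <- matching_rank(res)
    }
  }
  rank_distribution_set(ranks, iterations, "stochastic")
}

#' Gene-label permutation robustness analysis
#'
#' Repeatedly permutes gene labels (one random permutation per iteration,
#' applied consistently to every condition's means so each gene inherits
#' another gene's entire expression profile), recomputes ratios and
#' rankings, and summarizes the matching candidate's rank distribution.
#' Permutation destroys the association between expression and the
#' metabolic network, so the matching rank collapses to the tie/symmetry
#' expectation \code{(n + 1) / 2} — the null against which the real
#' rankings demonstrate gene-specific signal.
#'
#' @param model a \code{metabolic_model}.
#' @param baseline a \code{baseline_limits}.
#' @param expr an \code{expression_set} of condition means.
#' @param iterations number of permutations; default 1000.
#' @param seed integer seed.
#' @param conditions challenge conditions; default every condition naming a
#'   candidate.
#' @param per_condition when \code{TRUE}, draw an independent permutation
#'   for each condition instead of one shared permutation per iteration.
#' @param floor_epsilon optional minimum upper flux limit after scaling.
#' @return a \code{rank_distribution_set}.
#' @export
permutation_analysis <- function(model, baseline, expr, iterations = 1000,
                                 seed = NULL, conditions = NULL,
                                 per_condition = FALSE,
                                 floor_epsilon = NULL) {
  stopifnot(inherits(expr, "expression_set"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conditions))
    conditions <- intersect(expr$conditions, names(baseline$per_nutrient))
  if (length(conditions) == 0L)
    stop("no challenge condition names a candidate nutrient", call. = FALSE)
  ng <- length(expr$genes)
  ranks <- matrix(NA_real_, iterations, length(conditions),
                  dimnames = list(NULL, conditions))
  for (it in seq_len(iterations)) {
    perm <- sample.int(ng)
    pexpr <- permute_genes(expr, perm)
    for (cc in conditions) {
      if (per_condition && cc != conditions[1L]) {
        pexpr <- permute_genes(expr, sample.int(ng))
      }
      res <- prioritize(model, baseline, pexpr, cc, matching = cc,
                        floor_epsilon = floor_epsilon)
      ranks[it, cc] <- matching_rank(res)
    }
  }
  rank_distribution_set(ranks, iterations, "permutation")
}

#' Relabel genes of an expression set by a permutation
#'
#' Gene \code{i} receives the full expression profile (all condition means
#' and the max profile) of gene \code{perm[i]}. The identity permutation
#' returns an equivalent set.
#'
#' @param expr an \code{expression_set}.
#' @param perm integer permutation of \code{seq_along(expr$genes)}.
#' @return an \code{expression_set}.
#' @export
permute_genes <- function(expr, perm) {
  stopifnot(inherits(expr, "expression_set"),
            length(perm) == length(expr$genes))
  m <- expr$means[perm, , drop = FALSE]
  rownames(m) <- expr$genes
  expression_set(m)
}

rank_distribution_set <- function(ranks, iterations, mode) {
  per_condition <- lapply(colnames(ranks), function(cc) {
    r <- ranks[, cc]
    list(condition = cc, iterations = iterations, ranks = unname(r),
         mean = mean(r), sd = stats::sd(r))
  })
  names(per_condition) <- colnames(ranks)
  structure(list(per_condition = per_condition, mode = mode,
                 iterations = iterations,
                 grand_mean = mean(ranks)),
            class = "rank_distribution_set")
}

#' @export
print.rank_distribution_set <- function(x, ...) {
  cat("<rank_distribution_set> ", x$mode, " analysis, ", x$iterations,
      " iterations\n", sep = "")
  df <- data.frame(
    condition = names(x$per_condition),
    mean = round(vapply(x$per_condition, `[[`, 0, "mean"), 3),
    sd = round(vapply(x$per_condition, `[[`, 0, "sd"), 3))
  print(df, row.names = FALSE)
  cat("grand mean matching rank:", round(x$grand_mean, 3), "\n")
  invisible(x)
}

#' Summarize a robustness analysis
#'
#' @param object a \code{rank_distribution_set}.
#' @param ... unused.
#' @return data.frame of per-condition mean and sd of the matching rank.
#' @export
summary.rank_distribution_set <- function(object, ...) {
  data.frame(
    condition = names(object$per_condition),
    iterations = object$iterations,
    mean_rank = vapply(object$per_condition, `[[`, 0, "mean"),
    sd_rank = vapply(object$per_condition, `[[`, 0, "sd"),
    row.names = NULL)
}
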