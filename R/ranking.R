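#' Relative biomass production for one candidate nutrient
#'
#' The score at the heart of the prioritization: the optimal biomass
#' production under expression-scaled limits, divided by the baseline
#' optimum for the same nutrient, in percent:
#' \code{RBP(l, k) = 100 * F(scaled limits for k) / F_k}. Because scaled
#' limits are a subset of the baseline limits whenever all ratios are at
#' most 1, RBP never exceeds 100. A scaled problem made infeasible (for
#' example an unreachable ATPM requirement) scores 0 rather than erroring.
#'
#' @param model a \code{metabolic_model}.
#' @param baseline a \code{baseline_limits}.
#' @param ratios named per-reaction ratio vector for the challenge condition
#'   (see [reaction_ratios()]).
#' @param nutrient candidate name present in the baseline panel.
#' @param floor_epsilon optional minimum upper flux limit applied after
#'   scaling (see [apply_floor()]); \code{NULL} disables it.
#' @return RBP in percent.
#' @export
relative_biomass_production <- function(model, baseline, ratios, nutrient,
                                        floor_epsilon = NULL) {
  stopifnot(inherits(baseline, "baseline_limits"))
  info <- baseline$per_nutrient[[nutrient]]
  if (is.null(info))
    stop("nutrient '", nutrient, "' is not in the baseline panel", call. = FALSE)
  if (info$F_k <= 0)
    stop("candidate '", nutrient, "' has zero baseline biomass production",
         call. = FALSE)
  lim <- nutrient_limits(baseline, nutrient)
  scaled <- scale_limits(lim, ratios, protected = protected_reactions(model))
  if (!is.null(floor_epsilon)) scaled <- apply_floor(scaled, floor_epsilon)
  sol <- solve_fba(model, scaled, cap = baseline$cap)
  if (sol$status != "optimal") return(0)
  100 * sol$objective_value / info$F_k
}

#' Prioritize candidate nutrients for a challenge expression set
#'
#' Computes relative biomass production for every candidate of the baseline
#' panel under the challenge condition's expression-derived limits and
#' orders candidates by decreasing RBP. RBP values within \code{tie_tol} of
#' one another are treated as tied and receive their average rank, so LP
#' round-off cannot manufacture distinct ranks; exact ties are listed in
#' lexicographic nutrient order (an arbitrary, documented choice).
#'
#' @param model a \code{metabolic_model}.
#' @param baseline a \code{baseline_limits}.
#' @param expr an \code{expression_set}.
#' @param condition challenge condition label.
#' @param matching optional name of the candidate known to correspond to the
#'   challenge condition; defaults to the condition label when it names a
#'   candidate.
#' @param ratios precomputed ratio vector (computed from \code{expr} when
#'   \code{NULL}).
#' @param filter_alpha when non-\code{NULL}, apply the significance filter at
#'   this alpha (requires \code{matrix}).
#' @param matrix replicate-level \code{expression_matrix} for the filter.
#' @param floor_epsilon optional minimum upper flux limit after scaling.
#' @param tie_tol absolute RBP tolerance (percent) within which candidates
#'   tie; default 1e-4, comfortably above the round-off jitter of a
#'   double-precision simplex (observed up to ~1e-5 percent on problems
#'   with wide bound ranges) and far below any biologically meaningful
#'   RBP difference.
#' @return object of class \code{ranking_result}: data.frame \code{table}
#'   (nutrient, rbp, rank, is_matching) sorted by rank, plus
#'   \code{challenge_condition} and \code{matching_candidate}.
#' @examples
#' toy <- make_toy_model(panel_size = 2)
#' bl <- compute_baseline(toy$model, toy$candidates)
#' sim <- simulate_expression(toy, "glucose", sigma_log2 = 0, seed = 1)
#' expr <- condition_means(sim$matrix)
#' prioritize(toy$model, bl, expr, "glucose")
#' @export
prioritize <- function(model, baseline, expr, condition, matching = NULL,
                       ratios = NULL, filter_alpha = NULL, matrix = NULL,
                       floor_epsilon = NULL, tie_tol = 1e-4) {
  stopifnot(inherits(baseline, "baseline_limits"))
  nutrients <- names(baseline$per_nutrient)
  if (length(nutrients) < 2L)
    stop("prioritization needs at least two candidates", call. = FALSE)
  if (is.null(ratios)) ratios <- reaction_ratios(model, expr, condition)
  if (!is.null(filter_alpha)) {
    if (is.null(matrix))
      stop("the significance filter needs the replicate-level matrix",
           call. = FALSE)
    eligible <- significance_filter(model, matrix, expr, condition,
                                    alpha = filter_alpha)
    ratios[setdiff(names(ratios), eligible)] <- 1
  }
  rbp <- vapply(nutrients, function(k)
    relative_biomass_production(model, baseline, ratios, k,
                                floor_epsilon = floor_epsilon), 0)
  if (is.null(matching) && condition %in% nutrients) matching <- condition

  ord <- order(-rbp, nutrients)
  tbl <- data.frame(nutrient = nutrients[ord], rbp = unname(rbp[ord]),
                    stringsAsFactors = FALSE)
  tbl$rank <- tie_average_ranks(tbl$rbp, tie_tol)
  tbl$is_matching <- if (is.null(matching)) FALSE else tbl$nutrient == matching
  structure(list(table = tbl, challenge_condition = condition,
                 matching_candidate = matching,
                 n_scaled = sum(ratios < 1 - 1e-12)),
            class = "ranking_result")
}

# average ranks over groups of values (already sorted decreasing) that lie
# within tol of their group leader
tie_average_ranks <- function(sorted_desc, tol) {
  n <- length(sorted_desc)
  ranks <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && sorted_desc[i] - sorted_desc[j + 1L] <= tol) j <- j + 1L
    ranks[i:j] <- mean(i:j)
    i <- j + 1L
  }
  ranks
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("<ranking_result> challenge condition: ", x$challenge_condition, "\n",
      sep = "")
  tbl <- x$table
  tbl$rbp <- round(tbl$rbp, 2)
  print(tbl, row.names = FALSE)
  invisible(x)
}

#' Rank of the matching candidate
#'
#' @param result a \code{ranking_result}.
#' @return the tie-averaged rank of the matching candidate, or \code{NA}
#'   when none is declared.
#' @export
matching_rank <- function(result) {
  stopifnot(inherits(result, "ranking_result"))
  if (is.null(result$matching_candidate)) return(NA_real_)
  result$table$rank[result$table$is_matching][1L]
}

#' Matching versus non-matching growth summary
#'
#' Given rankings for several challenge conditions, compares each
#' candidate's relative biomass production under its matching expression set
#' with its mean RBP over the non-matching sets, and reports grand means —
#' the summary quantifying how adaptive the expression profiles are.
#'
#' @param results list of \code{ranking_result}, one per challenge condition,
#'   each with a declared matching candidate.
#' @return data.frame with one row per candidate that matches some condition
#'   (\code{nutrient}, \code{matching_rbp}, \code{nonmatching_mean}, the
#'   latter \code{NA} with a single condition) plus a final \code{mean} row.
#' @export
matching_analysis <- function(results) {
  if (inherits(results, "ranking_result")) results <- list(results)
  for (r in results)
    if (is.null(r$matching_candidate))
      stop("every ranking needs a declared matching candidate", call. = FALSE)
  conds <- vapply(results, `[[`, "", "challenge_condition")
  match_of <- vapply(results, `[[`, "", "matching_candidate")
  rows <- lapply(seq_along(results), function(i) {
    k <- match_of[i]
    own <- results[[i]]$table
    matching_rbp <- own$rbp[own$nutrient == k]
    others <- vapply(results[-i], function(r) {
      t <- r$table
      t$rbp[t$nutrient == k]
    }, 0)
    data.frame(nutrient = k, matching_rbp = matching_rbp,
               nonmatching_mean = if (length(others)) mean(others) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(nutrient = "mean",
                               matching_rbp = mean(out$matching_rbp),
                               nonmatching_mean =
                                 if (all(is.na(out$nonmatching_mean))) NA_real_
                                 else mean(out$nonmatching_mean)))
  out
}

#' Write a ranking report
#'
#' @param results a \code{ranking_result} or list thereof.
#' @param tsv,json optional output paths. The TSV has one row per
#'   (condition, nutrient) with columns \code{condition}, \code{nutrient},
#'   \code{rbp_percent}, \code{rank}, \code{is_matching}.
#' @return invisibly, the combined data.frame.
#' @export
write_ranking <- function(results, tsv = NULL, json = NULL) {
  if (inherits(results, "ranking_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(condition = r$challenge_condition,
               nutrient = r$table$nutrient,
               rbp_percent = r$table$rbp,
               rank = r$table$rank,
               is_matching = r$table$is_matching)
  }))
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(df)
}

#' Bar chart of a priority ordering
#'
#' Horizontal bars of relative biomass production, best candidate on top,
#' with the matching candidate highlighted.
#'
#' @param x a \code{ranking_result}.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ranking_result <- function(x, ...) {
  tbl <- x$table[rev(seq_len(nrow(x$table))), ]
  cols <- ifelse(tbl$is_matching, "forestgreen", "steelblue")
  graphics::barplot(tbl$rbp, names.arg = tbl$nutrient, horiz = TRUE,
                    col = cols, las = 1, xlab = "relative biomass production (%)",
                    main = paste("challenge:", x$challenge_condition), ...)
  invisible(x)
}
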