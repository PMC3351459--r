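#' Define a candidate-nutrient panel
#'
#' @param name character vector of nutrient names.
#' @param exchange character vector of exchange reaction ids, one per
#'   nutrient.
#' @param growth optional numeric vector of measured growth rates (1/h);
#'   \code{NA} entries fall back to the nominal rate at baseline computation.
#' @return data.frame with columns \code{name}, \code{exchange},
#'   \code{growth}.
#' @export
candidate_panel <- function(name, exchange, growth = NA_real_) {
  if (anyDuplicated(name)) stop("duplicate candidate names", call. = FALSE)
  data.frame(name = as.character(name), exchange = as.character(exchange),
             growth = rep_len(as.numeric(growth), length(name)),
             stringsAsFactors = FALSE)
}

#' Compute baseline flux limits over a candidate-nutrient panel
#'
#' The baseline limits estimate, for every reaction, the largest range of
#' fluxes encountered across near-optimal growth on any nutrient of the
#' panel; they play the role of maximal enzyme capacities. For each candidate
#' \code{k}, uptake of its exchange reaction is calibrated so that optimal
#' biomass production matches the measured growth rate (or the nominal rate
#' when none is supplied), with every other candidate's uptake closed; the
#' resulting optimum is recorded as \code{F_k}. Flux variability analysis at
#' the given optimality fraction then yields per-reaction ranges
#' \code{[vmin_k, vmax_k]}, and the baseline limits are the elementwise
#' envelope: \code{a_base = min_k vmin_k}, \code{b_base = max_k vmax_k}.
#' Because the limits represent enzyme capacities, they cap flux but never
#' force it: envelope lower limits are clamped at 0 from above (minimal
#' limits exist only where some condition drives a reversible reaction
#' backward) and upper limits at 0 from below, while hard model lower
#' bounds such as the ATPM maintenance requirement are preserved.
#' Non-candidate exchanges (the mineral medium) stay open at the model's
#' default bounds throughout.
#'
#' @param model a \code{metabolic_model}.
#' @param candidates a [candidate_panel()] data.frame.
#' @param fraction optimality fraction for the variability step; default 0.9.
#' @param nominal_growth growth-rate target (1/h) for candidates without a
#'   measurement; default 0.5.
#' @param cap finite cap for unbounded bounds.
#' @return object of class \code{baseline_limits}: \code{a_base},
#'   \code{b_base} (named per reaction), \code{per_nutrient} (per-candidate
#'   list with calibrated exchange bounds and baseline optimum \code{F_k}),
#'   plus the panel and parameters used.
#' @examples
#' toy <- make_toy_model(panel_size = 2)
#' bl <- compute_baseline(toy$model, toy$candidates)
#' bl$per_nutrient$glucose$F_k
#' @export
compute_baseline <- function(model, candidates, fraction = 0.9,
                             nominal_growth = 0.5, cap = 1000) {
  stopifnot(inherits(model, "metabolic_model"))
  if (nrow(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  ex_idx <- vapply(candidates$exchange, reaction_index, 1L,
                   ids = model$reaction_ids)
  not_ex <- setdiff(ex_idx, model$exchange_reactions)
  if (length(not_ex))
    stop("panel entries are not exchange reactions: ",
         paste(model$reaction_ids[not_ex], collapse = ", "), call. = FALSE)

  # medium with every candidate's uptake closed; mineral exchanges untouched
  base <- resolve_bounds(model_limits(model), cap)
  base$lower[ex_idx] <- pmax(base$lower[ex_idx], 0)

  n <- length(model$reaction_ids)
  a_base <- rep(Inf, n)
  b_base <- rep(-Inf, n)
  per_nutrient <- list()
  for (i in seq_len(nrow(candidates))) {
    nm <- candidates$name[i]
    j <- ex_idx[i]
    target <- candidates$growth[i]
    if (is.na(target)) target <- nominal_growth
    cal <- tryCatch(
      calibrate_uptake(model, j, target_growth = target, limits = base,
                       cap = cap),
      error = function(e) stop("baseline failed for candidate '", nm, "': ",
                               conditionMessage(e), call. = FALSE))
    lim_k <- base
    lim_k$lower[j] <- cal$lower
    sol <- solve_fba(model, lim_k, cap = cap)
    if (sol$status != "optimal")
      stop("baseline failed for candidate '", nm, "': FBA ", sol$status,
           call. = FALSE)
    F_k <- sol$objective_value
    fva <- flux_variability(model, lim_k, fraction = fraction,
                            objective_opt = F_k, cap = cap)
    a_base <- pmin(a_base, fva$vmin)
    b_base <- pmax(b_base, fva$vmax)
    per_nutrient[[nm]] <- list(exchange = model$reaction_ids[j],
                               exchange_index = j,
                               uptake = cal$uptake,
                               lower = cal$lower, upper = cal$upper,
                               F_k = F_k, target_growth = target)
  }
  # The envelope caps capacity; it must not force flux. A reaction that never
  # ran backward in any near-optimal condition has no reverse capacity
  # (lower limit 0), but a positive vmin (e.g. biomass, which every FVA run
  # holds at >= fraction * F_k) is not a minimum requirement, so lower
  # limits are clamped at <= 0; symmetrically upper limits at >= 0. Hard
  # model lower bounds (ATPM maintenance, forced uptakes) are preserved.
  a_base <- pmax(base$lower, pmin(a_base, 0))
  b_base <- pmin(base$upper, pmax(b_base, 0))

  structure(list(
    a_base = stats::setNames(a_base, model$reaction_ids),
    b_base = stats::setNames(b_base, model$reaction_ids),
    per_nutrient = per_nutrient,
    candidates = candidates,
    fraction = fraction, nominal_growth = nominal_growth, cap = cap,
    base_lower = base$lower, base_upper = base$upper
  ), class = "baseline_limits")
}

#' @export
print.baseline_limits <- function(x, ...) {
  cat("<baseline_limits> ", length(x$a_base), " reactions, ",
      length(x$per_nutrient), " candidate nutrients (fraction ", x$fraction,
      ")\n", sep = "")
  Fk <- vapply(x$per_nutrient, `[[`, 0, "F_k")
  print(round(Fk, 4))
  invisible(x)
}

#' Nutrient-specific limits from a baseline
#'
#' Takes the baseline envelope and sets the exchange bounds for one candidate
#' to its calibrated values, closing uptake (lower bound 0) for every other
#' candidate in the panel so the nutrient is evaluated as sole carbon source.
#' Secretion through other candidates' exchanges remains possible.
#'
#' @param baseline a \code{baseline_limits}.
#' @param nutrient candidate name.
#' @return a \code{limit_vectors}.
#' @export
nutrient_limits <- function(baseline, nutrient) {
  stopifnot(inherits(baseline, "baseline_limits"))
  info <- baseline$per_nutrient[[nutrient]]
  if (is.null(info))
    stop("nutrient '", nutrient, "' is not in the baseline panel", call. = FALSE)
  lo <- baseline$a_base
  up <- baseline$b_base
  for (nm in names(baseline$per_nutrient)) {
    j <- baseline$per_nutrient[[nm]]$exchange_index
    if (nm == nutrient) {
      lo[j] <- info$lower
      up[j] <- max(up[j], info$upper, 0)
    } else {
      lo[j] <- 0
      up[j] <- max(up[j], 0)
    }
  }
  limit_vectors(lo, up, names(baseline$a_base))
}

#' Scale flux limits by relative expression
#'
#' Applies per-reaction expression ratios (in [0, 1]) to a limit vector:
#' positive upper bounds shrink to \code{ratio * upper} and negative lower
#' bounds to \code{ratio * lower}, so enzyme capacity limits both directions
#' of a reversible reaction symmetrically. Protected reactions (exchanges,
#' ATPM, any enzyme-free reaction the caller designates) and reactions
#' without a ratio pass through unchanged. Scaling never creates capacity: a
#' zero bound stays zero whatever the ratio.
#'
#' @param limits a \code{limit_vectors} (typically from [nutrient_limits()]).
#' @param ratios named numeric vector of per-reaction ratios in [0, 1]
#'   (names are reaction ids; see [reaction_ratios()]).
#' @param protected reaction ids or indices exempt from scaling.
#' @return a scaled \code{limit_vectors}.
#' @export
scale_limits <- function(limits, ratios, protected = integer(0)) {
  stopifnot(inherits(limits, "limit_vectors"))
  ids <- limits$reaction_ids
  if (is.null(ids)) stop("limits must carry reaction ids", call. = FALSE)
  if (any(ratios < 0 | ratios > 1, na.rm = TRUE))
    stop("ratios must lie in [0, 1]", call. = FALSE)
  prot <- if (is.character(protected)) match(protected, ids) else as.integer(protected)
  r <- rep(1, length(ids))
  pos <- match(names(ratios), ids)
  r[pos[!is.na(pos)]] <- ratios[!is.na(pos)]
  r[is.na(r)] <- 1
  r[prot[!is.na(prot)]] <- 1
  lo <- limits$lower
  up <- limits$upper
  shrink_up <- up > 0
  up[shrink_up] <- r[shrink_up] * up[shrink_up]
  shrink_lo <- lo < 0
  lo[shrink_lo] <- r[shrink_lo] * lo[shrink_lo]
  limit_vectors(lo, up, ids)
}

#' Apply a minimum upper flux limit
#'
#' Raises every positive upper bound below \code{epsilon} up to
#' \code{epsilon}. This simulates the presence of a small amount of enzyme
#' for reactions whose baseline limits are tiny (typically cofactor
#' synthesis), and is the alternative to removing cofactor constituents from
#' the biomass reaction; off by default in the pipeline.
#'
#' @param limits a \code{limit_vectors}.
#' @param epsilon floor in mmol/gDW/h; default 0.03.
#' @return a \code{limit_vectors}.
#' @seealso [remove_biomass_constituents()]
#' @export
apply_floor <- function(limits, epsilon = 0.03) {
  stopifnot(inherits(limits, "limit_vectors"))
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("epsilon must be nonnegative", call. = FALSE)
  up <- limits$upper
  raise <- up > 0 & up < epsilon
  up[raise] <- epsilon
  limit_vectors(limits$lower, up, limits$reaction_ids)
}

#' Protected reactions for expression scaling
#'
#' Exchange reactions and the ATPM reaction are never scaled by expression:
#' exchanges are environmental interfaces (uptake is fixed by calibration)
#' and the ATPM lower bound is a hard maintenance requirement.
#'
#' @param model a \code{metabolic_model}.
#' @param extra additional reaction ids to protect (e.g. spontaneous
#'   diffusion reactions).
#' @return integer vector of reaction indices.
#' @export
protected_reactions <- function(model, extra = character(0)) {
  idx <- model$exchange_reactions
  if (!is.na(model$atpm_reaction)) idx <- c(idx, model$atpm_reaction)
  if (length(extra))
    idx <- c(idx, vapply(extra, reaction_index, 1L, ids = model$reaction_ids))
  sort(unique(idx))
}

#' Export baseline limits
#'
#' Writes the per-reaction envelope as TSV (\code{reaction}, \code{a_base},
#' \code{b_base}) and, optionally, a JSON file carrying the per-nutrient
#' calibration block (uptake, exchange bounds, baseline optimum).
#'
#' @param baseline a \code{baseline_limits}.
#' @param tsv,json output paths (either may be \code{NULL}).
#' @return invisibly, the paths written.
#' @export
write_baseline <- function(baseline, tsv = NULL, json = NULL) {
  stopifnot(inherits(baseline, "baseline_limits"))
  if (!is.null(tsv)) {
    df <- data.frame(reaction = names(baseline$a_base),
                     a_base = unname(baseline$a_base),
                     b_base = unname(baseline$b_base))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      fraction = baseline$fraction,
      nominal_growth = baseline$nominal_growth,
      a_base = as.list(baseline$a_base),
      b_base = as.list(baseline$b_base),
      per_nutrient = baseline$per_nutrient
    ), json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(tsv = tsv, json = json))
}
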