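# Shared fixtures. The 2-candidate toy is used wherever the decoys are
# irrelevant; builds are cached per test file run.
toy2 <- function(...) make_toy_model(panel_size = 2, seed = 1, ...)

toy2_baseline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- toy2()
      cache <<- list(toy = toy,
                     baseline = compute_baseline(toy$model, toy$candidates))
    }
    cache
  }
})

# limits with a single candidate exchange open at the given uptake
sole_carbon_limits <- function(fixture, nutrient, uptake = 10) {
  model <- fixture$model
  lim <- resolve_bounds(model_limits(model))
  ex <- vapply(fixture$candidates$exchange,
               function(id) match(id, model$reaction_ids), 1L)
  lim$lower[ex] <- 0
  j <- match(fixture$candidates$exchange[fixture$candidates$name == nutrient],
             model$reaction_ids)
  lim$lower[j] <- -uptake
  lim
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (!is.null(x$children)) x$children <- lapply(x$children, unclass_deep)
  x
}

# random GPR tree generator for property tests
random_gpr <- function(depth, genes = sprintf("g%02d", 1:20)) {
  if (depth <= 0 || stats::runif(1) < 0.35) {
    return(structure(list(kind = "gene", gene = sample(genes, 1)),
                     class = "gpr"))
  }
  kind <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  children <- lapply(seq_len(k), function(i) random_gpr(depth - 1, genes))
  # collapse children of the same kind the way the parser canonicalizes
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr")
}
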