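#' Deterministic toy metabolic network with a candidate-nutrient panel
#'
#' A small network capturing the structure that makes carbon-source
#' inference possible: glucose and acetate transport, lumped glycolysis
#' (with isozymes), a pyruvate-dehydrogenase step, a lumped TCA/energy
#' reaction (catalyzed by a complex or an isozyme, exercising nested GPR
#' rules), a glyoxylate-shunt analogue required for growth on acetate but
#' unused during optimal growth on glucose, an anabolic precursor step, and
#' a biomass reaction drawing a sugar precursor, an acetyl unit and energy
#' units. Decoy candidates beyond the two real carbons are exchange
#' metabolites funneled into central metabolism through seeded two-step
#' chains (transporter plus converter, each with its own gene) with
#' randomized carbon yields, giving a spread of baseline uptake rates.
#' Stoichiometries of the core network are fixed in code so oracle values
#' stay stable; only the decoy yields depend on the seed.
#'
#' Build-time invariants are verified: both real carbons support growth,
#' optimal glucose growth carries zero flux through the shunt analogue, and
#' growth on acetate is impossible with the shunt closed.
#'
#' @param panel_size number of candidate nutrients (>= 2); the first two are
#'   the glucose and acetate analogues, the rest decoys. Default 18.
#' @param with_atpm include an ATP-maintenance reaction with a fixed lower
#'   bound of 0.2 mmol/gDW/h.
#' @param with_cofactor add a cofactor-synthesis reaction and a
#'   small-coefficient cofactor term (0.005) to the biomass reaction,
#'   reproducing the tiny-flux bottleneck that motivates cofactor removal
#'   or the minimum-upper-limit floor.
#' @param seed integer seed controlling the decoy yields.
#' @return object of class \code{toy_fixture}: \code{model}
#'   (a \code{metabolic_model}), \code{candidates} (a [candidate_panel()]),
#'   \code{real_carbons} (names of the two informative candidates) and
#'   \code{params}.
#' @export
make_toy_model <- function(panel_size = 18, with_atpm = FALSE,
                           with_cofactor = FALSE, seed = 1) {
  if (panel_size < 2) stop("panel_size must be at least 2", call. = FALSE)
  n_decoy <- panel_size - 2L

  mets <- c("glc_e", "ac_e", "glc_c", "pyr_c", "accoa_c", "prec_c", "atp_c")
  rxn <- list()
  add <- function(id, sto, lower, upper, gpr = NULL) {
    rxn[[id]] <<- list(sto = sto, lower = lower, upper = upper, gpr = gpr)
  }
  # exchanges ship with uptake closed (a defined medium without carbon);
  # analyses open the candidate under study
  add("EX_glc", c(glc_e = -1), 0, 1000)
  add("EX_ac", c(ac_e = -1), 0, 1000)
  # candidate-specific steps carry one gene each (chains of equal length
  # stay exchangeable under gene-label permutation); the isozyme and
  # complex GPR forms live on the shared energy reactions
  add("GLCT", c(glc_e = -1, glc_c = 1), 0, 1000, "gGlcT")
  add("ACT", c(ac_e = -1, accoa_c = 1), 0, 1000, "gAcT")
  add("GLYC", c(glc_c = -1, pyr_c = 2, atp_c = 2), 0, 1000, "gGly")
  add("PDH", c(pyr_c = -1, accoa_c = 1), 0, 1000, "gPdh1 or gPdh2")
  add("TCA", c(accoa_c = -1, atp_c = 3), 0, 1000, "(gTca1 and gTca2) or gTca3")
  # glyoxylate-shunt analogue lumped with anaplerosis: acetyl units to the
  # biomass precursor, the only precursor route that bypasses pyruvate
  add("SHUNT", c(accoa_c = -2, atp_c = -1, prec_c = 1), 0, 1000, "gIcl")
  add("PREC", c(pyr_c = -1, atp_c = -1, prec_c = 1), 0, 1000, "gPrec")

  set.seed(seed)
  decoys <- character(0)
  if (n_decoy > 0) {
    # decoys enter central metabolism through one lumped transport +
    # degradation step (a single gene each, like the real carbons' entry
    # reactions) with seeded carbon yields; alternating sugar-like (hexose
    # node) and acid-like (pyruvate node) entry points mirror the chemical
    # spread of a realistic candidate panel
    yields <- stats::runif(n_decoy, 0.3, 1.2)
    feeds <- rep_len(c("glc_c", "pyr_c"), n_decoy)
    for (i in seq_len(n_decoy)) {
      nm <- sprintf("dec%02d", i)
      decoys <- c(decoys, nm)
      mets <- c(mets, paste0(nm, "_e"))
      add(paste0("EX_", nm), stats::setNames(-1, paste0(nm, "_e")),
          0, 1000)
      add(paste0("T_", nm),
          stats::setNames(c(-1, yields[i]), c(paste0(nm, "_e"), feeds[i])),
          0, 1000, paste0("gT", nm))
    }
  }

  biomass_sto <- c(prec_c = -1, accoa_c = -1, atp_c = -2)
  if (with_cofactor) {
    mets <- c(mets, "cof_c")
    add("COFS", c(atp_c = -1, cof_c = 1), 0, 1000, "gCof")
    biomass_sto <- c(biomass_sto, cof_c = -0.005)
  }
  add("BIOMASS", biomass_sto, 0, 1000)
  if (with_atpm) add("ATPM", c(atp_c = -1), 0.2, 1000)

  ids <- names(rxn)
  S <- matrix(0, length(mets), length(ids), dimnames = list(mets, ids))
  lower <- upper <- numeric(length(ids))
  gpr <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    r <- rxn[[j]]
    S[names(r$sto), j] <- r$sto
    lower[j] <- r$lower
    upper[j] <- r$upper
    if (!is.null(r$gpr)) gpr[[j]] <- parse_gpr(r$gpr)
  }
  model <- metabolic_model(mets, ids, S, lower, upper, gpr = gpr,
                           biomass_reaction = "BIOMASS",
                           atpm_reaction = if (with_atpm) "ATPM" else NULL)

  candidates <- candidate_panel(
    name = c("glucose", "acetate", decoys),
    exchange = c("EX_glc", "EX_ac", if (n_decoy) paste0("EX_", decoys)))

  fixture <- structure(list(model = model, candidates = candidates,
                            real_carbons = c("glucose", "acetate"),
                            params = list(panel_size = panel_size,
                                          with_atpm = with_atpm,
                                          with_cofactor = with_cofactor,
                                          seed = seed)),
                       class = "toy_fixture")
  verify_toy_fixture(fixture)
  fixture
}

# growth on both real carbons; shunt unused on glucose, essential on acetate
verify_toy_fixture <- function(fixture) {
  model <- fixture$model
  sole <- function(nutrient, shunt_max = NULL) {
    lim <- resolve_bounds(model_limits(model))
    ex_idx <- vapply(fixture$candidates$exchange, reaction_index, 1L,
                     ids = model$reaction_ids)
    lim$lower[ex_idx] <- 0
    j <- reaction_index(model$reaction_ids,
                        fixture$candidates$exchange[
                          fixture$candidates$name == nutrient])
    lim$lower[j] <- -10
    if (!is.null(shunt_max))
      lim$upper[reaction_index(model$reaction_ids, "SHUNT")] <- shunt_max
    solve_fba(model, lim)
  }
  sglc <- sole("glucose")
  sac <- sole("acetate")
  if (sglc$status != "optimal" || sglc$objective_value <= 1e-6)
    stop("toy fixture invariant violated: no growth on glucose", call. = FALSE)
  if (sac$status != "optimal" || sac$objective_value <= 1e-6)
    stop("toy fixture invariant violated: no growth on acetate", call. = FALSE)
  if (abs(sglc$fluxes["SHUNT"]) > 1e-6)
    stop("toy fixture invariant violated: shunt active on glucose", call. = FALSE)
  sac0 <- sole("acetate", shunt_max = 0)
  if (sac0$status == "optimal" && sac0$objective_value > 1e-6)
    stop("toy fixture invariant violated: acetate grows without the shunt",
         call. = FALSE)
  invisible(fixture)
}

#' @export
print.toy_fixture <- function(x, ...) {
  cat("<toy_fixture> panel of ", nrow(x$candidates), " candidates (",
      paste(x$real_carbons, collapse = ", "), " + ",
      nrow(x$candidates) - 2L, " decoys), seed ", x$params$seed, "\n",
      sep = "")
  print(x$model)
  invisible(x)
}

#' Simulate condition-adaptive expression for the toy fixture
#'
#' Emulates the structure of a multi-condition microarray study: one
#' condition per real carbon, with the glucose analogue measured in five
#' replicates and every other condition in two (mirroring the unequal
#' replicate design of the motivating data set). Within each condition,
#' genes of reactions that carry flux at the optimal growth solution for
#' that condition's carbon source are expressed at \code{baseline_level *
#' fold}; genes of unused reactions sit at \code{baseline_level}, except on
#' the preferred sugar (the glucose analogue) where they are
#' catabolite-repressed to \code{baseline_level / fold} — the adaptive
#' pattern of enteric bacteria: the shunt-analogue gene behaves like
#' isocitrate lyase (high on acetate, strongly repressed on glucose), and
#' alternative-carbon transporters are repressed on glucose and merely
#' basal elsewhere. Replicates are drawn log-normally: log2 values get
#' independent Gaussian noise of sd \code{sigma_log2}. Expression is on an
#' arbitrary linear scale, since only ratios enter the method; with
#' \code{fold = 1} the matrix is flat and carries no information.
#'
#' @param fixture a \code{toy_fixture}.
#' @param true_nutrient the challenge carbon source (must be a real carbon
#'   of the fixture with nonzero baseline growth); recorded as the
#'   challenge label.
#' @param sigma_log2 replicate noise sd on the log2 scale; default 0.1.
#' @param fold adaptive up-regulation factor; default 8.
#' @param seed integer seed.
#' @param baseline_level linear-scale expression of non-induced genes;
#'   default 100.
#' @param replicates named integer vector of replicates per condition;
#'   default 5 for the glucose analogue, 2 otherwise.
#' @param n_background number of background genes (present on the array but
#'   absent from every GPR) expressed at \code{baseline_level} in all
#'   conditions; default 200. These emulate the dominant uninformative
#'   fraction of a real transcriptome — in the kind of data set this
#'   simulator mirrors, well under a tenth of the genes change between
#'   carbon sources — and they matter for the permutation null: permuting
#'   labels over a realistic gene pool hands mostly uninformative profiles
#'   to the enzyme genes, which is what destroys the ranking signal.
#' @param bg_sigma_log2 between-condition biological variability (log2 sd)
#'   of background genes; default 0.3, i.e. condition means of "unchanged"
#'   genes still wobble within about two-fold — variation that a
#'   two-replicate t-test would not call significant, as in the data this
#'   simulator mirrors.
#' @return object of class \code{simulated_expression}: \code{matrix} (an
#'   \code{expression_matrix} over all real-carbon conditions),
#'   \code{true_nutrient}, and \code{params}.
#' @export
simulate_expression <- function(fixture, true_nutrient, sigma_log2 = 0.1,
                                fold = 8, seed = 1, baseline_level = 100,
                                replicates = NULL, n_background = 200,
                                bg_sigma_log2 = 0.3) {
  stopifnot(inherits(fixture, "toy_fixture"))
  conds <- fixture$real_carbons
  if (!true_nutrient %in% conds)
    stop("unknown challenge nutrient '", true_nutrient,
         "'; real carbons are: ", paste(conds, collapse = ", "),
         call. = FALSE)
  if (is.null(replicates))
    replicates <- stats::setNames(ifelse(conds == "glucose", 5L, 2L), conds)

  model <- fixture$model
  genes <- unique(unlist(lapply(model$gpr, function(g)
    if (is.null(g)) NULL else gpr_genes(g))))
  if (n_background > 0)
    genes <- c(genes, sprintf("bg%04d", seq_len(n_background)))

  # per condition: which genes belong to flux-carrying reactions at the
  # optimal solution for sole growth on that carbon
  set.seed(seed)
  active_genes <- lapply(conds, function(cc) {
    lim <- resolve_bounds(model_limits(model))
    ex_idx <- vapply(fixture$candidates$exchange, reaction_index, 1L,
                     ids = model$reaction_ids)
    lim$lower[ex_idx] <- 0
    j <- reaction_index(model$reaction_ids,
                        fixture$candidates$exchange[
                          fixture$candidates$name == cc])
    lim$lower[j] <- -10
    sol <- solve_fba(model, lim)
    used <- which(abs(sol$fluxes) > 1e-6)
    unique(unlist(lapply(model$gpr[used], function(g)
      if (is.null(g)) NULL else gpr_genes(g))))
  })
  names(active_genes) <- conds

  preferred <- "glucose"
  background <- grepl("^bg[0-9]+$", genes)
  samples <- character(0); sample_cond <- character(0)
  cols <- list()
  for (cc in conds) {
    active <- genes %in% active_genes[[cc]]
    # enzyme genes: induced when used, catabolite-repressed on the
    # preferred sugar when unused; background genes: baseline plus mild
    # sub-significant condition-to-condition wobble
    level <- ifelse(background, baseline_level,
                    ifelse(active, baseline_level * fold,
                           if (cc == preferred) baseline_level / fold
                           else baseline_level))
    mean_log2 <- log2(level)
    mean_log2[background] <- mean_log2[background] +
      stats::rnorm(sum(background), sd = bg_sigma_log2)
    for (r in seq_len(replicates[[cc]])) {
      sid <- sprintf("%s_r%d", cc, r)
      samples <- c(samples, sid)
      sample_cond <- c(sample_cond, cc)
      cols[[sid]] <- 2^(mean_log2 + stats::rnorm(length(genes),
                                                 sd = sigma_log2))
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- genes
  mat <- expression_matrix(vals, sample_cond)
  structure(list(matrix = mat, true_nutrient = true_nutrient,
                 params = list(sigma_log2 = sigma_log2, fold = fold,
                               seed = seed, baseline_level = baseline_level,
                               replicates = as.list(replicates))),
            class = "simulated_expression")
}

#' @export
print.simulated_expression <- function(x, ...) {
  cat("<simulated_expression> challenge: ", x$true_nutrient,
      " (fold ", x$params$fold, ", sigma_log2 ", x$params$sigma_log2,
      ", seed ", x$params$seed, ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Write a toy fixture to disk
#'
#' Emits the model in the package JSON dialect, the simulated expression as
#' TSV, and a YAML manifest recording the seed and parameters. Outputs are
#' deterministic given the seeds: identical seeds give byte-identical
#' files.
#'
#' @param fixture a \code{toy_fixture}.
#' @param sim optional \code{simulated_expression} to write alongside.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_toy_fixture <- function(fixture, sim = NULL, dir) {
  stopifnot(inherits(fixture, "toy_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(model = file.path(dir, "model.json"),
             manifest = file.path(dir, "manifest.yaml"))
  write_model_json(fixture$model, paths[["model"]])
  manifest <- list(fixture = fixture$params,
                   candidates = fixture$candidates$name,
                   real_carbons = fixture$real_carbons)
  if (!is.null(sim)) {
    paths["expression"] <- file.path(dir, "expression.tsv")
    write_expression_tsv(sim$matrix, paths[["expression"]])
    manifest$expression <- c(list(true_nutrient = sim$true_nutrient),
                             sim$params)
  }
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}
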