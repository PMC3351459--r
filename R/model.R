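#' Construct a metabolic model
#'
#' The central container for constraint-based analysis: a stoichiometric
#' matrix \code{S} (metabolites x reactions, flux units mmol/gDW/h), default
#' flux bounds, reversibility flags, parsed GPR rules, and the indices of the
#' biomass reaction, the exchange reactions and (optionally) the
#' non-growth-associated ATP maintenance (ATPM) reaction. Exchange reactions
#' connect a single external metabolite to the environment; by convention
#' negative exchange flux is uptake and positive flux is secretion.
#'
#' @param metabolite_ids,reaction_ids character vectors of unique identifiers.
#' @param S numeric matrix, \code{S[i, j]} = stoichiometric coefficient of
#'   metabolite \code{i} in reaction \code{j}.
#' @param lower,upper numeric vectors of default flux bounds per reaction;
#'   \code{-Inf}/\code{Inf} are allowed and resolved to a finite cap before
#'   solving (see [resolve_bounds()]).
#' @param gpr list (one entry per reaction) of \code{gpr} trees or \code{NULL}
#'   for reactions without gene association.
#' @param biomass_reaction id or index of the biomass reaction.
#' @param atpm_reaction optional id or index of the ATPM reaction; its lower
#'   bound is treated as a hard maintenance requirement and is never scaled.
#' @return an object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, S, lower, upper,
                            gpr = NULL, biomass_reaction,
                            atpm_reaction = NULL) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  n <- length(reaction_ids)
  m <- length(metabolite_ids)
  if (is.null(gpr)) gpr <- vector("list", n)
  rownames(S) <- metabolite_ids
  colnames(S) <- reaction_ids
  model <- structure(list(
    metabolite_ids = as.character(metabolite_ids),
    reaction_ids = as.character(reaction_ids),
    S = S,
    lower = as.numeric(lower),
    upper = as.numeric(upper),
    gpr = gpr,
    biomass_reaction = reaction_index(reaction_ids, biomass_reaction),
    atpm_reaction = if (is.null(atpm_reaction)) NA_integer_ else
      reaction_index(reaction_ids, atpm_reaction)
  ), class = "metabolic_model")
  model$reversible <- model$lower < 0
  model$exchange_reactions <- find_exchanges(model)
  validate_model(model)
  model
}

reaction_index <- function(ids, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (x < 1L || x > length(ids)) stop("reaction index out of range", call. = FALSE)
    return(x)
  }
  i <- match(x, ids)
  if (is.na(i)) stop(sprintf("unknown reaction id '%s'", x), call. = FALSE)
  i
}

# exchange reactions: touch exactly one metabolite
find_exchanges <- function(model) {
  nz <- colSums(model$S != 0)
  which(nz == 1L)
}

validate_model <- function(model) {
  n <- length(model$reaction_ids)
  m <- length(model$metabolite_ids)
  if (anyDuplicated(model$reaction_ids))
    stop("duplicate reaction ids", call. = FALSE)
  if (anyDuplicated(model$metabolite_ids))
    stop("duplicate metabolite ids", call. = FALSE)
  if (!all(dim(model$S) == c(m, n)))
    stop("S has dimensions inconsistent with metabolite/reaction ids", call. = FALSE)
  if (length(model$lower) != n || length(model$upper) != n)
    stop("bound vectors must have one entry per reaction", call. = FALSE)
  zero <- which(colSums(model$S != 0) == 0L)
  if (length(zero))
    stop("reaction(s) with all-zero stoichiometry column: ",
         paste(model$reaction_ids[zero], collapse = ", "), call. = FALSE)
  if (any(model$lower > model$upper))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(model$reaction_ids[model$lower > model$upper], collapse = ", "),
         call. = FALSE)
  if (is.na(model$biomass_reaction))
    stop("biomass reaction not identified; supply an explicit reaction id",
         call. = FALSE)
  if (length(model$gpr) != n)
    stop("gpr list must have one entry per reaction", call. = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions\n", sep = "")
  cat("  biomass: ", x$reaction_ids[x$biomass_reaction],
      "; exchanges: ", length(x$exchange_reactions),
      "; with GPR: ", sum(!vapply(x$gpr, is.null, TRUE)), "\n", sep = "")
  if (!is.na(x$atpm_reaction))
    cat("  ATPM: ", x$reaction_ids[x$atpm_reaction],
        " (lower bound ", x$lower[x$atpm_reaction], ")\n", sep = "")
  invisible(x)
}

#' Read a metabolic model from file
#'
#' Supports two formats: the package's versioned JSON dialect (see
#' [write_model_json()]) and SBML Level 2/3. For SBML, GPR rules are taken
#' from \code{fbc:geneProductAssociation} elements when present, falling back
#' to \code{GENE_ASSOCIATION} strings in reaction notes; flux bounds come from
#' \code{fbc} bound parameters, kinetic-law \code{LOWER_BOUND}/
#' \code{UPPER_BOUND} parameters, or the \code{reversible} attribute.
#' Species flagged \code{boundaryCondition="true"} are dropped from the
#' stoichiometric matrix, which turns boundary-connected reactions into
#' exchange reactions.
#'
#' @param path path to the model file.
#' @param format \code{"auto"} (by extension), \code{"json"} or \code{"sbml"}.
#' @param biomass optional explicit biomass reaction id; otherwise the
#'   objective-flagged reaction in the file is used.
#' @param atpm optional ATPM reaction id.
#' @return a \code{metabolic_model}.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       biomass = NULL, atpm = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
         json = read_model_json(path, biomass = biomass, atpm = atpm),
         sbml = read_model_sbml(path, biomass = biomass, atpm = atpm))
}

#' Write a metabolic model in the package JSON dialect
#'
#' A small versioned schema (\code{fluxprior-model/1}): metabolites are listed
#' by id; each reaction carries a stoichiometry map, bounds, its canonical GPR
#' string (absent when there is none) and optional \code{objective} /
#' \code{atpm} flags. [read_model()] on the output reproduces the model
#' exactly (stoichiometry, bounds, GPR canonical strings).
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    coefs <- model$S[, j]
    coefs <- coefs[coefs != 0]
    r <- list(id = model$reaction_ids[j],
              stoichiometry = as.list(coefs),
              lower = model$lower[j], upper = model$upper[j])
    if (!is.null(model$gpr[[j]])) r$gpr <- gpr_to_string(model$gpr[[j]])
    if (j == model$biomass_reaction) r$objective <- TRUE
    if (!is.na(model$atpm_reaction) && j == model$atpm_reaction) r$atpm <- TRUE
    r
  })
  obj <- list(schema = "fluxprior-model/1",
              metabolites = lapply(model$metabolite_ids, function(id) list(id = id)),
              reactions = rxns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_model_json <- function(path, biomass = NULL, atpm = NULL) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("unparsable JSON model '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  if (is.null(obj$metabolites) || is.null(obj$reactions))
    stop("JSON model '", path, "' lacks 'metabolites' or 'reactions'", call. = FALSE)
  met_ids <- vapply(obj$metabolites, function(m) as.character(m$id), "")
  n <- length(obj$reactions)
  rxn_ids <- vapply(obj$reactions, function(r) as.character(r$id), "")
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, rxn_ids))
  lower <- numeric(n); upper <- numeric(n)
  gpr <- vector("list", n)
  bio <- NULL; atpm_id <- NULL
  for (j in seq_len(n)) {
    r <- obj$reactions[[j]]
    st <- r$stoichiometry
    if (is.null(st) || length(st) == 0L)
      stop("reaction '", rxn_ids[j], "' has empty stoichiometry", call. = FALSE)
    mets <- names(st)
    bad <- setdiff(mets, met_ids)
    if (length(bad))
      stop("reaction '", rxn_ids[j], "' references unknown metabolite(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    S[mets, j] <- as.numeric(unlist(st))
    lower[j] <- if (is.null(r$lower)) -Inf else as.numeric(r$lower)
    upper[j] <- if (is.null(r$upper)) Inf else as.numeric(r$upper)
    if (!is.null(r$gpr) && nzchar(r$gpr)) gpr[[j]] <- parse_gpr(r$gpr)
    if (isTRUE(r$objective)) bio <- rxn_ids[j]
    if (isTRUE(r$atpm)) atpm_id <- rxn_ids[j]
  }
  if (!is.null(biomass)) bio <- biomass
  if (is.null(bio))
    stop("biomass reaction not identifiable in '", path,
         "'; pass biomass = \"<reaction id>\"", call. = FALSE)
  if (!is.null(atpm)) atpm_id <- atpm
  metabolic_model(met_ids, rxn_ids, S, lower, upper, gpr = gpr,
                  biomass_reaction = bio, atpm_reaction = atpm_id)
}

read_model_sbml <- function(path, biomass = NULL, atpm = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparsable SBML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ns <- xml2::xml_ns(doc)
  # strip namespace prefixes for robust matching across SBML levels
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp) == 0L) stop("SBML '", path, "' contains no species", call. = FALSE)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  met_ids <- sp_id[!sp_boundary]

  # fbc parameter-valued bounds (SBML L3)
  pars <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  # fbc active objective
  obj_rxn <- NULL
  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  if (length(fo)) {
    rids <- xml2::xml_attr(fo, "reaction")
    if (length(rids)) obj_rxn <- rids[[1L]]
  }
  # fbc gene product labels
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- stats::setNames(xml2::xml_attr(gps, "label"), xml2::xml_attr(gps, "id"))
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]

  rx <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx) == 0L) stop("SBML '", path, "' contains no reactions", call. = FALSE)
  n <- length(rx)
  rxn_ids <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, rxn_ids))
  lower <- numeric(n); upper <- numeric(n)
  gpr <- vector("list", n)
  bio <- if (!is.null(biomass)) biomass else obj_rxn

  for (j in seq_len(n)) {
    node <- rx[[j]]
    add_side <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        sto <- xml2::xml_attr(ref, "stoichiometry")
        sto <- if (is.na(sto)) 1 else as.numeric(sto)
        if (sid %in% met_ids) S[sid, j] <<- S[sid, j] + sign * sto
      }
    }
    add_side("./*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1)
    add_side("./*[local-name()='listOfProducts']/*[local-name()='speciesReference']", +1)

    rev <- !(xml2::xml_attr(node, "reversible") %in% c("false", "0"))
    lb <- NA_real_; ub <- NA_real_
    # fbc attribute bounds referencing parameters
    attrs <- xml2::xml_attrs(node)
    lbp <- attrs[grepl("lowerFluxBound$", names(attrs))]
    ubp <- attrs[grepl("upperFluxBound$", names(attrs))]
    if (length(lbp) && lbp[[1L]] %in% names(par_val)) lb <- par_val[[lbp[[1L]]]]
    if (length(ubp) && ubp[[1L]] %in% names(par_val)) ub <- par_val[[ubp[[1L]]]]
    # legacy kinetic-law parameters
    if (is.na(lb) || is.na(ub)) {
      kp <- xml2::xml_find_all(node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      if (length(kp)) {
        kid <- xml2::xml_attr(kp, "id")
        kval <- as.numeric(xml2::xml_attr(kp, "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kval[match("LOWER_BOUND", kid)]
        if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kval[match("UPPER_BOUND", kid)]
        if ("OBJECTIVE_COEFFICIENT" %in% kid && is.null(bio) &&
            isTRUE(kval[match("OBJECTIVE_COEFFICIENT", kid)] != 0))
          bio <- rxn_ids[j]
      }
    }
    lower[j] <- if (is.na(lb)) (if (rev) -Inf else 0) else lb
    upper[j] <- if (is.na(ub)) Inf else ub

    # GPR: fbc geneProductAssociation wins over notes
    gpa <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      s <- sbml_gpa_to_string(xml2::xml_children(gpa)[[1L]], gp_label)
      if (nzchar(s)) gpr[[j]] <- parse_gpr(s)
    } else {
      notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexpr("GENE[_ ]ASSOCIATION\\s*:\\s*[^<\n]*", txt))
        if (length(m)) {
          rule <- trimws(sub("^GENE[_ ]ASSOCIATION\\s*:\\s*", "", m))
          if (nzchar(rule)) gpr[[j]] <- parse_gpr(rule)
        }
      }
    }
  }
  if (is.null(bio))
    stop("biomass reaction not identifiable in '", path,
         "'; pass biomass = \"<reaction id>\"", call. = FALSE)
  metabolic_model(met_ids, rxn_ids, S, lower, upper, gpr = gpr,
                  biomass_reaction = bio, atpm_reaction = atpm)
}

sbml_gpa_to_string <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- gp_label[ref]
    return(if (is.na(lab)) ref else unname(lab))
  }
  parts <- vapply(xml2::xml_children(node), sbml_gpa_to_string, "",
                  gp_label = gp_label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Remove constituents from the biomass reaction
#'
#' Zeroes the stoichiometric coefficients of the given metabolites in the
#' biomass column, leaving every other reaction untouched. This is the
#' standard workaround for cofactor bottlenecks: cofactors and prosthetic
#' groups have very small biomass coefficients, so the reactions that
#' synthesize them carry tiny baseline flux limits which, once scaled by
#' relative expression, can choke growth artificially. For the iAF1260
#' E. coli reconstruction the conventional list of 15 such constituents is
#' available from [iaf1260_biomass_cofactors()].
#'
#' @param model a \code{metabolic_model}.
#' @param metabolite_ids metabolite ids to remove; each must occur in the
#'   biomass reaction with nonzero coefficient.
#' @return a modified copy of \code{model}.
#' @seealso [apply_floor()] for the alternative minimum-upper-limit approach.
#' @export
remove_biomass_constituents <- function(model, metabolite_ids) {
  stopifnot(inherits(model, "metabolic_model"))
  if (length(metabolite_ids) == 0L) return(model)
  j <- model$biomass_reaction
  idx <- match(metabolite_ids, model$metabolite_ids)
  missing <- metabolite_ids[is.na(idx) | model$S[ifelse(is.na(idx), 1L, idx), j] == 0]
  if (length(missing))
    stop("metabolite(s) absent from the biomass reaction: ",
         paste(missing, collapse = ", "), call. = FALSE)
  model$S[idx, j] <- 0
  validate_model(model)
  model
}

#' Cofactor constituents of the iAF1260 biomass reaction
#'
#' The 15 metabolites of the iAF1260 biomass function categorized as
#' "Cofactors, Prosthetic groups and others" (collectively under 2.9% of
#' biomass by weight), with their stoichiometric coefficients
#' (mmol/gDW). Pass the \code{metabolite} column to
#' [remove_biomass_constituents()] when working with iAF1260.
#'
#' @return data.frame with columns \code{metabolite} (BiGG cytosolic id),
#'   \code{name}, and \code{coefficient}.
#' @export
iaf1260_biomass_cofactors <- function() {
  data.frame(
    metabolite = c("10fthf_c", "2ohph_c", "amet_c", "coa_c", "fad_c",
                   "mlthf_c", "nad_c", "nadp_c", "pheme_c", "pydx5p_c",
                   "ribflv_c", "sheme_c", "thf_c", "thmpp_c", "udcpdp_c"),
    name = c("10-formyltetrahydrofolate", "2-octaprenyl-6-hydroxyphenol",
             "S-adenosylmethionine", "coenzyme A", "FAD",
             "5,10-methylenetetrahydrofolate", "NAD", "NADP", "protoheme",
             "pyridoxal 5'-phosphate", "riboflavin", "siroheme",
             "tetrahydrofolate", "thiamine diphosphate",
             "undecaprenyl pyrophosphate"),
    coefficient = c(0.000223, 0.000223, 0.000223, 0.000576, 0.000223,
                    0.000223, 0.001831, 0.000447, 0.000223, 0.000223,
                    0.000223, 0.000223, 0.000223, 0.000223, 0.000055),
    stringsAsFactors = FALSE
  )
}
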