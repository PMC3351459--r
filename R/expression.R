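#' Construct an expression matrix
#'
#' Gene-by-sample linear-scale expression with a sample-to-condition map.
#'
#' @param values numeric matrix (genes x samples), nonnegative, with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param conditions character vector of condition labels, one per sample.
#' @return object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, conditions) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("values must have unique gene ids as rownames", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (length(conditions) != ncol(values))
    stop("one condition label per sample is required", call. = FALSE)
  if (any(values < 0, na.rm = TRUE) || anyNA(values))
    stop("expression values must be nonnegative and complete", call. = FALSE)
  structure(list(values = values,
                 conditions = stats::setNames(as.character(conditions),
                                              colnames(values))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(unique(x$conditions)), " conditions)\n", sep = "")
  invisible(x)
}

#' Read a gene-by-sample expression table
#'
#' Tab-separated, linear-scale values: first column gene ids, remaining
#' columns one sample each, with sample ids in the header row. The
#' sample-to-condition map comes either from a comment line
#' \code{#condition: sample=label sample=label ...} preceding the header,
#' from the \code{conditions} argument, or from a YAML sidecar mapping file
#' given as \code{conditions_file}. Ragged rows, non-numeric or negative
#' entries and duplicate gene ids are rejected with the offending line
#' number.
#'
#' @param path TSV file path.
#' @param conditions optional named character vector (names = sample ids).
#' @param conditions_file optional YAML file of \code{sample: label} pairs.
#' @return an \code{expression_matrix}.
#' @export
read_expression <- function(path, conditions = NULL, conditions_file = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  cond_line <- grep("^#condition:", lines)
  cmap <- NULL
  if (length(cond_line)) {
    spec <- trimws(sub("^#condition:", "", lines[cond_line[1L]]))
    pairs <- strsplit(strsplit(spec, "[ \t]+")[[1L]], "=", fixed = TRUE)
    cmap <- stats::setNames(vapply(pairs, `[`, "", 2L),
                            vapply(pairs, `[`, "", 1L))
  }
  if (!is.null(conditions_file)) {
    cmap <- unlist(yaml::read_yaml(conditions_file))
  }
  if (!is.null(conditions)) cmap <- conditions

  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(rows) < 2L) stop("expression file has no data rows", call. = FALSE)
  header <- rows[[1L]]
  samples <- header[-1L]
  ncols <- length(header)
  genes <- character(length(rows) - 1L)
  vals <- matrix(NA_real_, length(rows) - 1L, length(samples))
  for (i in 2:length(rows)) {
    row <- rows[[i]]
    if (length(row) != ncols)
      stop(sprintf("line %d: expected %d fields, found %d",
                   lineno[i], ncols, length(row)), call. = FALSE)
    genes[i - 1L] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric expression value", lineno[i]),
           call. = FALSE)
    if (any(v < 0))
      stop(sprintf("line %d: negative expression value", lineno[i]),
           call. = FALSE)
    vals[i - 1L, ] <- v
  }
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  rownames(vals) <- genes
  colnames(vals) <- samples
  if (is.null(cmap))
    stop("no sample-to-condition map: add a '#condition:' line, a sidecar ",
         "YAML, or pass conditions=", call. = FALSE)
  missing <- setdiff(samples, names(cmap))
  if (length(missing))
    stop("samples without condition label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  expression_matrix(vals, unname(cmap[samples]))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: emits the \code{#condition:} map line, the
#' sample header, and one row per gene.
#'
#' @param matrix an \code{expression_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#condition: ",
                    paste(names(matrix$conditions), matrix$conditions,
                          sep = "=", collapse = " ")), con)
  writeLines(paste(c("gene", colnames(matrix$values)), collapse = "\t"), con)
  apply_rows <- cbind(rownames(matrix$values),
                      format(matrix$values, trim = TRUE, digits = 15))
  writeLines(apply(apply_rows, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Condition means of an expression matrix
#'
#' Averages replicate samples within each condition on the log scale and
#' exponentiates: \code{mean_gl = 2^(mean of log2 values)} — the geometric
#' mean of the replicates. Also records, per gene, the maximum of the
#' condition means across all supplied conditions, the estimate of each
#' gene's expression range used for relative-expression ratios.
#'
#' @param matrix an \code{expression_matrix}; all values must be positive
#'   (floor zeros first via \code{floor_value}).
#' @param floor_value optional small positive value substituted for
#'   non-positive entries before taking logs.
#' @return object of class \code{expression_set}: \code{means} (genes x
#'   conditions), \code{max_profile} (per-gene max), \code{genes},
#'   \code{conditions}.
#' @export
condition_means <- function(matrix, floor_value = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  vals <- matrix$values
  if (any(vals <= 0)) {
    if (is.null(floor_value))
      stop("expression contains non-positive values; supply floor_value ",
           "(a small positive constant) to floor them before the log",
           call. = FALSE)
    vals[vals <= floor_value] <- floor_value
  }
  conds <- unique(unname(matrix$conditions))
  lv <- log2(vals)
  means <- matrix(NA_real_, nrow(vals), length(conds),
                  dimnames = list(rownames(vals), conds))
  for (cc in conds) {
    cols <- which(matrix$conditions == cc)
    means[, cc] <- 2^rowMeans(lv[, cols, drop = FALSE])
  }
  expression_set(means)
}

#' Construct an expression set from condition means
#'
#' @param means numeric matrix of linear-scale condition means (genes x
#'   conditions) with dimnames.
#' @param max_profile optional externally supplied per-gene maximum; default
#'   the row maximum over the supplied conditions.
#' @return object of class \code{expression_set}.
#' @export
expression_set <- function(means, max_profile = NULL) {
  means <- as.matrix(means)
  if (any(means < 0)) stop("condition means must be nonnegative", call. = FALSE)
  if (is.null(max_profile)) {
    max_profile <- apply(means, 1, max)
  } else {
    max_profile <- pmax(max_profile[rownames(means)], apply(means, 1, max))
  }
  structure(list(genes = rownames(means), conditions = colnames(means),
                 means = means,
                 max_profile = stats::setNames(max_profile, rownames(means))),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", length(x$genes), " genes x ",
      length(x$conditions), " conditions: ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-reaction expression ratios for one condition
#'
#' Aggregates condition-mean gene expression into reaction-level values via
#' each reaction's GPR (\code{or} = sum over isozymes, \code{and} = min over
#' complex subunits, applied recursively), then divides the challenge
#' condition's reaction value by the maximum reaction value across all
#' conditions. Reactions without a GPR, with no measured gene, or with an
#' all-zero denominator are unconstrained (ratio 1). The result always lies
#' in [0, 1], with ratio exactly 1 in each reaction's maximum-achieving
#' condition.
#'
#' @param model a \code{metabolic_model}.
#' @param expr an \code{expression_set}.
#' @param condition challenge condition label (must be a column of
#'   \code{expr$means}).
#' @return named numeric vector of ratios, one per model reaction.
#' @export
reaction_ratios <- function(model, expr, condition) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(expr, "expression_set"))
  if (!condition %in% expr$conditions)
    stop("condition '", condition, "' not present in expression set",
         call. = FALSE)
  e <- reaction_expression(model, expr)
  ratios <- rep(1, length(model$reaction_ids))
  names(ratios) <- model$reaction_ids
  has <- !is.na(e[, 1L])
  emax <- apply(e, 1, max)
  ok <- has & emax > 0
  ratios[ok] <- pmin(1, e[ok, condition] / emax[ok])
  ratios
}

# reaction x condition matrix of GPR-aggregated expression; NA for reactions
# without GPR or with no measured gene
reaction_expression <- function(model, expr) {
  out <- matrix(NA_real_, length(model$reaction_ids), length(expr$conditions),
                dimnames = list(model$reaction_ids, expr$conditions))
  cols <- lapply(expr$conditions, function(cc)
    stats::setNames(expr$means[, cc], rownames(expr$means)))
  names(cols) <- expr$conditions
  for (j in seq_along(model$reaction_ids)) {
    g <- model$gpr[[j]]
    if (is.null(g)) next
    for (cc in expr$conditions) {
      out[j, cc] <- eval_gpr(g, cols[[cc]])
    }
  }
  out
}

#' Significance filter for expression scaling
#'
#' Restricts scaling to reactions whose expression change is statistically
#' significant: for each reaction with a GPR, the replicate-level log2 values
#' of each governing gene in the challenge condition are compared with those
#' in the condition attaining the reaction's maximum aggregated expression,
#' by a two-sided Welch two-sample t-test. A reaction is eligible for
#' scaling when any of its genes gives p < \code{alpha}; otherwise its ratio
#' should be left at 1. Reactions whose maximum-achieving condition is the
#' challenge condition itself, or for which no gene has at least two
#' replicates in both conditions, are not eligible (their test is skipped).
#'
#' @param model a \code{metabolic_model}.
#' @param matrix the replicate-level \code{expression_matrix}.
#' @param expr the matching \code{expression_set} of condition means.
#' @param condition challenge condition label.
#' @param alpha significance cut-off; default 0.05.
#' @return character vector of reaction ids eligible for scaling.
#' @export
significance_filter <- function(model, matrix, expr, condition,
                                alpha = 0.05) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(expr, "expression_set"))
  e <- reaction_expression(model, expr)
  lv <- log2(pmax(matrix$values, .Machine$double.xmin))
  cols_of <- split(seq_along(matrix$conditions), unname(matrix$conditions))
  eligible <- character(0)
  for (j in seq_along(model$reaction_ids)) {
    g <- model$gpr[[j]]
    if (is.null(g) || is.na(e[j, 1L])) next
    max_cond <- expr$conditions[which.max(e[j, ])]
    if (identical(max_cond, condition)) next
    a_cols <- cols_of[[condition]]
    b_cols <- cols_of[[max_cond]]
    if (length(a_cols) < 2L || length(b_cols) < 2L) next
    genes <- intersect(gpr_genes(g), rownames(lv))
    for (gene in genes) {
      xa <- lv[gene, a_cols]
      xb <- lv[gene, b_cols]
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      } else {
        p <- stats::t.test(xa, xb, var.equal = FALSE)$p.value
      }
      if (!is.na(p) && p < alpha) {
        eligible <- c(eligible, model$reaction_ids[j])
        break
      }
    }
  }
  eligible
}

#' Export reaction ratios as TSV
#'
#' @param ratios named ratio vector from [reaction_ratios()].
#' @param condition condition label recorded in the table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ratios_tsv <- function(ratios, condition, path) {
  df <- data.frame(reaction = names(ratios), condition = condition,
                   ratio = unname(ratios))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
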