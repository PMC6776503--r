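# Module-level summarization of omics feature matrices (first-PC eigengenes)
# and assembly of the endophenotype matrix used by the screening stage.

ENDO_CATEGORIES <- c("pathology", "acetylation-module", "methylation-module",
                     "expression-module", "miRNA", "protein")

#' Endophenotype matrix
#'
#' Individuals x variables container for the screening set: brain
#' pathologies, omics module eigengenes, and single-analyte miRNA/protein
#' levels, with a category tag per variable.
#'
#' @param values numeric matrix, individuals in rows (rownames = sample ids),
#'   variables in columns.
#' @param meta data.frame with columns \code{variable} and \code{category};
#'   categories come from the fixed vocabulary (pathology,
#'   acetylation-module, methylation-module, expression-module, miRNA,
#'   protein).
#' @return object of class \code{endophenotype_matrix}.
#' @export
endophenotype_matrix <- function(values, meta) {
  stopifnot(is.matrix(values), is.data.frame(meta),
            all(c("variable", "category") %in% names(meta)),
            ncol(values) == nrow(meta))
  if (anyDuplicated(meta$variable)) {
    stop("variable ids must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(meta$category), ENDO_CATEGORIES)
  if (length(bad)) {
    stop("unknown endophenotype category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  colnames(values) <- meta$variable
  structure(list(values = values, meta = meta),
            class = "endophenotype_matrix")
}

#' @export
print.endophenotype_matrix <- function(x, ...) {
  cat(sprintf("endophenotype_matrix: %d individuals x %d variables\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$meta$category))
  invisible(x)
}

#' Summarize features into module eigengenes
#'
#' For each module the member features are mean-imputed, standardized, and
#' summarized by the first principal component across individuals (the
#' conventional module eigengene). Eigengenes are scaled to unit variance
#' and oriented so the mean correlation with member features is positive;
#' an exactly zero mean correlation falls back to the sign of the loading of
#' the lexicographically first feature.
#'
#' @param features individuals x features numeric matrix (rownames = sample
#'   ids, colnames = feature ids).
#' @param modules data.frame with columns \code{feature} and \code{module}
#'   mapping each assigned feature to one module label; features absent from
#'   the mapping are ignored.
#' @param category category tag attached to every resulting eigengene
#'   (default "acetylation-module").
#' @return an \code{endophenotype_matrix} with one column per module.
#' @export
eigengene <- function(features, modules, category = "acetylation-module") {
  stopifnot(is.matrix(features), is.data.frame(modules),
            all(c("feature", "module") %in% names(modules)))
  missing_feat <- setdiff(modules$feature, colnames(features))
  if (length(missing_feat)) {
    stop("assigned features absent from matrix: ",
         paste(head(missing_feat, 5), collapse = ", "), call. = FALSE)
  }
  labs <- sort(unique(modules$module))
  n <- nrow(features)
  out <- matrix(NA_real_, n, length(labs),
                dimnames = list(rownames(features), labs))
  for (i in seq_along(labs)) {
    feats <- sort(modules$feature[modules$module == labs[i]])
    x <- features[, feats, drop = FALSE]
    # mean-impute then standardize each feature
    for (j in seq_len(ncol(x))) {
      v <- x[, j]
      if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
      s <- sd(v)
      if (is.na(s) || s == 0) {
        stop(sprintf("module %s has zero-variance feature %s",
                     labs[i], feats[j]), call. = FALSE)
      }
      x[, j] <- (v - mean(v)) / s
    }
    sv <- svd(x, nu = 1, nv = 0)
    e <- sv$u[, 1] * sv$d[1]
    e <- e / sd(e)
    mc <- mean(cor(e, x))
    flip <- if (mc < 0) -1 else if (mc > 0) 1 else sign(cor(e, x[, 1]))
    out[, i] <- flip * e
  }
  endophenotype_matrix(out, data.frame(variable = labs, category = category,
                                       stringsAsFactors = FALSE))
}

#' Assemble the endophenotype screening matrix
#'
#' Column-binds pathology measures, module eigengenes, and single-analyte
#' layers on the intersection of individuals, preserving category metadata.
#'
#' @param ... \code{endophenotype_matrix} objects (at least one non-empty).
#' @return a combined \code{endophenotype_matrix}; the per-category variable
#'   counts are logged.
#' @export
assemble_endophenotypes <- function(...) {
  parts <- Filter(function(p) !is.null(p) && ncol(p$values) > 0, list(...))
  if (!length(parts)) stop("no endophenotype inputs supplied", call. = FALSE)
  for (p in parts) stopifnot(inherits(p, "endophenotype_matrix"))
  ids <- Reduce(intersect, lapply(parts, function(p) rownames(p$values)))
  if (!length(ids)) stop("empty intersection of individuals", call. = FALSE)
  vals <- do.call(cbind, lapply(parts, function(p) p$values[ids, , drop = FALSE]))
  meta <- do.call(rbind, lapply(parts, function(p) p$meta))
  if (anyDuplicated(meta$variable)) {
    stop("duplicated variable id across inputs: ",
         paste(unique(meta$variable[duplicated(meta$variable)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(meta$category)
  log_msg("omics", "assembled %d variables over %d individuals (%s)",
          nrow(meta), length(ids),
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  endophenotype_matrix(vals, meta)
}

#' Make an endophenotype matrix from a plain table of single variables
#'
#' Convenience wrapper tagging every column of a numeric table (e.g. the 14
#' pathology measures, or miRNA / protein levels) with one category.
#'
#' @param tab data.frame or matrix with sample ids as rownames.
#' @param category one of the endophenotype categories.
#' @return an \code{endophenotype_matrix}.
#' @export
as_endophenotypes <- function(tab, category) {
  m <- as.matrix(tab)
  endophenotype_matrix(m, data.frame(variable = colnames(m),
                                     category = category,
                                     stringsAsFactors = FALSE))
}
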