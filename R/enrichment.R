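# GREAT-style functional enrichment of histone-peak modules: assign peaks to
# genes by basal-plus-extension cis-regulatory domains, then test gene sets
# with hypergeometric (gene-based) and binomial (region-based) upper tails,
# BH FDR control, and fold-enrichment reporting.

#' Cis-regulatory domain rule
#'
#' Basal-plus-extension convention: every gene gets a strand-aware basal
#' domain around its TSS (5 kb upstream / 1 kb downstream by default),
#' extended in both directions to the nearest neighboring basal domain or by
#' at most \code{max_extension} bp, whichever is closer.
#'
#' @param basal_upstream,basal_downstream,max_extension extents in bp.
#' @return list of class \code{regdomain_rule}.
#' @export
regdomain_rule <- function(basal_upstream = 5000, basal_downstream = 1000,
                           max_extension = 1e6) {
  if (any(c(basal_upstream, basal_downstream, max_extension) <= 0)) {
    stop("all rule extents must be positive", call. = FALSE)
  }
  if (max_extension < max(basal_upstream, basal_downstream)) {
    stop("max_extension must be >= the basal extents", call. = FALSE)
  }
  structure(list(basal_upstream = basal_upstream,
                 basal_downstream = basal_downstream,
                 max_extension = max_extension),
            class = "regdomain_rule")
}

#' Build per-gene regulatory domains
#'
#' @param genes data.frame with columns \code{gene}, \code{chr}, \code{tss},
#'   \code{strand} ("+" or "-").
#' @param rule a \code{regdomain_rule}.
#' @return data.frame gene, chr, start, end (1-based inclusive) with basal
#'   bounds kept as \code{basal_start}/\code{basal_end}.
#' @export
regulatory_domains <- function(genes, rule = regdomain_rule()) {
  need <- c("gene", "chr", "tss", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("gene table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(genes$strand)) || !all(genes$strand %in% c("+", "-"))) {
    stop("every gene needs strand '+' or '-'", call. = FALSE)
  }
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - rule$basal_upstream,
                        genes$tss - rule$basal_downstream)
  basal_end <- ifelse(plus, genes$tss + rule$basal_downstream,
                      genes$tss + rule$basal_upstream)
  basal_start <- pmax(basal_start, 1)

  start <- end <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- which(genes$chr == genes$chr[i])
    same <- setdiff(same, i)
    # extension stops at the nearest neighboring basal domain, capped
    left_limit <- basal_end[same][basal_end[same] < basal_start[i]]
    left <- max(basal_start[i] - rule$max_extension,
                if (length(left_limit)) max(left_limit) + 1 else -Inf, 1)
    right_limit <- basal_start[same][basal_start[same] > basal_end[i]]
    right <- min(basal_end[i] + rule$max_extension,
                 if (length(right_limit)) min(right_limit) - 1 else Inf)
    start[i] <- min(left, basal_start[i])
    end[i] <- max(right, basal_end[i])
  }
  data.frame(gene = genes$gene, chr = genes$chr, start = start, end = end,
             basal_start = basal_start, basal_end = basal_end,
             stringsAsFactors = FALSE)
}

#' Assign peaks to genes by domain overlap of the peak midpoint
#'
#' A peak maps to every gene whose regulatory domain contains the peak
#' midpoint; multi-assignment is allowed. With \code{mode = "any_overlap"} a
#' peak maps to every gene whose domain overlaps any part of it.
#'
#' @param peaks data.frame with columns \code{peak}, \code{chr},
#'   \code{start}, \code{end} (1-based inclusive).
#' @param domains output of \code{\link{regulatory_domains}}.
#' @param mode \code{"midpoint"} (default) or \code{"any_overlap"}.
#' @return data.frame \code{peak}, \code{gene} (zero rows for unassigned
#'   peaks).
#' @export
assign_peaks <- function(peaks, domains, mode = c("midpoint", "any_overlap")) {
  mode <- match.arg(mode)
  need <- c("peak", "chr", "start", "end")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    stop("peak table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(peaks$start) | is.na(peaks$end) | peaks$start > peaks$end)
  if (length(bad)) {
    stop("malformed peak interval at row ", bad[1], call. = FALSE)
  }
  mid <- floor((peaks$start + peaks$end) / 2)
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    hit <- domains$chr == peaks$chr[i] &
      (if (mode == "midpoint") {
        domains$start <= mid[i] & domains$end >= mid[i]
      } else {
        domains$start <= peaks$end[i] & domains$end >= peaks$start[i]
      })
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peak = peaks$peak[i], gene = domains$gene[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(peak = character(), gene = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment of a peak module
#'
#' Gene-based hypergeometric test: the universe is the set of genes hit by
#' any peak; successes are the term's genes in the universe; draws are the
#' genes hit by the module's peaks; upper-tail p. Region-based binomial
#' test: per-peak success probability is the fraction of all peaks whose
#' assigned genes include a term gene; observed is the number of module
#' peaks hitting the term; upper-tail p. Fold enrichment is
#' observed/expected. Benjamini-Hochberg q-values are computed across terms
#' within each method.
#'
#' @param module_peaks character vector of peak ids in the module (must be a
#'   subset of \code{all_peaks}).
#' @param all_peaks character vector of all peak ids on the assay.
#' @param mapping peak-to-gene mapping from \code{\link{assign_peaks}}.
#' @param genesets named list of gene-id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param method which test(s) to run; default both.
#' @param fdr significance flag threshold (default 0.05).
#' @return data.frame sorted by q: term, method, observed, expected, fold,
#'   p, q, significant.
#' @export
test_enrichment <- function(module_peaks, all_peaks, mapping, genesets,
                            method = c("hypergeometric", "binomial"),
                            fdr = 0.05) {
  method <- match.arg(method, several.ok = TRUE)
  if (!all(module_peaks %in% all_peaks)) {
    stop("module peaks must be a subset of all peaks", call. = FALSE)
  }
  map <- mapping[mapping$peak %in% all_peaks, , drop = FALSE]
  universe <- unique(map$gene)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  module_genes <- unique(map$gene[map$peak %in% module_peaks])
  peak_genes <- split(map$gene, map$peak)

  rows <- list()
  for (term in names(genesets)) {
    tg <- intersect(genesets[[term]], universe)
    if (!length(tg)) {
      warning("term '", term, "' has no genes in the universe; skipped")
      next
    }
    if ("hypergeometric" %in% method) {
      N <- length(universe); K <- length(tg)
      n <- length(module_genes)
      k <- length(intersect(module_genes, tg))
      expected <- n * K / N
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, method = "hypergeometric", observed = k,
        expected = expected, fold = if (expected > 0) k / expected else NA,
        p = p, stringsAsFactors = FALSE)
    }
    if ("binomial" %in% method) {
      hits_term <- vapply(peak_genes, function(g) any(g %in% tg), logical(1))
      pi0 <- mean(all_peaks %in% names(peak_genes)[hits_term])
      n <- length(module_peaks)
      k <- sum(module_peaks %in% names(peak_genes)[hits_term])
      expected <- n * pi0
      p <- if (pi0 >= 1) 1 else pbinom(k - 1, n, pi0, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, method = "binomial", observed = k, expected = expected,
        fold = if (expected > 0) k / expected else NA, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(term = character(), method = character(),
                      observed = integer(), expected = numeric(),
                      fold = numeric(), p = numeric(), q = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (m in unique(out$method)) {
    sel <- out$method == m
    out$q[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out$significant <- out$q < fdr
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
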