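# End-to-end orchestration: simulate -> omics -> motorscore -> score ->
# scan -> screen -> mediate -> network -> enrich, from a single config, with
# per-stage manifests (parameters, seeds, input checksums, row counts) and a
# resume contract (a stage is skipped when its outputs are newer than its
# inputs and the config is unchanged).

PIPELINE_STAGES <- c("simulate", "omics", "motorscore", "score", "scan",
                     "screen", "mediate", "network", "enrich")

#' Pipeline configuration
#'
#' Every analysis threshold is surfaced as a named key with its conventional
#' default: clump r^2 0.1, window 2000 kb, PRS inclusion thresholds up to 1
#' with 0.5 as the headline, scan alpha 0.001, screen alpha 0.05, FDR 0.05.
#'
#' @param sim a \code{simulation_spec} (or list of its arguments).
#' @param stages which stages to run (a prefix of the stage order).
#' @param clump_r2,clump_kb LD clumping parameters.
#' @param thresholds PRS inclusion p-value series.
#' @param headline_threshold threshold used for screening/mediation/network.
#' @param scan_alpha,screen_alpha,fdr significance settings.
#' @param bn_boot,bn_restarts,bn_consensus bootstrap-network settings.
#' @param seed master seed (overridable in \code{\link{run_pipeline}}).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = simulation_spec(),
                            stages = PIPELINE_STAGES,
                            clump_r2 = 0.1, clump_kb = 2000,
                            thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1,
                                           0.5, 1.0),
                            headline_threshold = 0.5,
                            scan_alpha = 0.001, screen_alpha = 0.05,
                            fdr = 0.05, bn_boot = 100L, bn_restarts = 2L,
                            bn_consensus = 0.5, seed = 1L) {
  if (is.list(sim) && !inherits(sim, "simulation_spec")) {
    sim <- do.call(simulation_spec, sim)
  }
  pos <- match(stages, PIPELINE_STAGES)
  if (anyNA(pos) || !identical(sort(pos), seq_along(pos))) {
    stop("stages must form a prefix of: ",
         paste(PIPELINE_STAGES, collapse = " -> "), call. = FALSE)
  }
  structure(list(sim = sim, stages = PIPELINE_STAGES[sort(pos)],
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 thresholds = thresholds,
                 headline_threshold = headline_threshold,
                 scan_alpha = scan_alpha, screen_alpha = screen_alpha,
                 fdr = fdr, bn_boot = as.integer(bn_boot),
                 bn_restarts = as.integer(bn_restarts),
                 bn_consensus = bn_consensus, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{pipeline_config}};
#' \code{sim} holds \code{\link{simulation_spec}} arguments
#' (\code{mediation_weights} as a mapping name -> [a, b]).
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$mediation_weights)) {
      y$sim$mediation_weights <- lapply(y$sim$mediation_weights, as.numeric)
    }
    if (!is.null(y$sim$covariate_effects)) {
      y$sim$covariate_effects <- unlist(y$sim$covariate_effects)
    }
    if (!is.null(y$sim$maf_range)) y$sim$maf_range <- as.numeric(y$sim$maf_range)
  }
  do.call(pipeline_config, y)
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_fresh <- function(dir, stage, digest, inputs, outputs) {
  man <- file.path(dir, sprintf("manifest_%s.json", stage))
  if (!file.exists(man) || !all(file.exists(outputs))) return(FALSE)
  rec <- tryCatch(jsonlite::read_json(man), error = function(e) NULL)
  if (is.null(rec) || !identical(rec$config_digest, digest)) return(FALSE)
  if (length(inputs) && any(file.exists(inputs))) {
    if (min(file.mtime(outputs)) < max(file.mtime(inputs))) return(FALSE)
  }
  TRUE
}

write_stage_manifest <- function(dir, stage, digest, inputs, outputs, extra) {
  rec <- c(list(stage = stage, config_digest = digest,
                inputs = as.list(unname(inputs)),
                input_md5 = as.list(unname(tools::md5sum(inputs))),
                outputs = as.list(unname(outputs))), extra)
  write_json_file(rec, file.path(dir, sprintf("manifest_%s.json", stage)))
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order under \code{out_dir},
#' writing TSV outputs plus a JSON manifest per stage and an overall run
#' manifest. A stage whose outputs are up to date under the same config is
#' skipped. Stage failures halt the run with the stage named; earlier
#' outputs are preserved.
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory (created if needed).
#' @param seed optional master-seed override.
#' @return the run manifest (list), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$sim$seed <- as.integer(seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- config_digest(config)
  ran <- list()
  for (stage in config$stages) {
    fn <- get(sprintf("stage_%s", stage), mode = "function")
    res <- tryCatch(fn(config, out_dir, digest),
                    error = function(e) {
                      stop(sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE)
                    })
    log_msg("pipeline", "stage %s: %s", stage,
            if (isTRUE(res$skipped)) "skipped (up to date)" else "done")
    ran[[stage]] <- res
  }
  manifest <- list(config_digest = digest, seed = config$seed,
                   stages = lapply(ran, function(r) r[c("skipped", "outputs")]))
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

pfile <- function(dir, ...) file.path(dir, sprintf(...))

stage_simulate <- function(config, dir, digest) {
  outs <- c(pfile(dir, "genotypes.vcf"), pfile(dir, "sumstats.tsv"),
            pfile(dir, "phenotypes.tsv"), pfile(dir, "endophenotypes.tsv"),
            pfile(dir, "endophenotype_meta.tsv"), pfile(dir, "truth.json"),
            pfile(dir, "features_acetyl.tsv"), pfile(dir, "modules_acetyl.tsv"),
            pfile(dir, "peaks.bed"), pfile(dir, "peak_modules.tsv"),
            pfile(dir, "genes.tsv"), pfile(dir, "genesets.gmt"))
  if (stage_fresh(dir, "simulate", digest, character(0), outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  spec <- config$sim
  geno <- simulate_genotypes(spec)
  stats <- simulate_gwas(geno, spec)
  cohort <- simulate_cohort(geno, stats, spec)

  write_vcf(geno, outs[1])
  write_sumstats(stats, outs[2])
  write_tsv(cohort$phenotypes, outs[3])
  write_tsv(as.data.frame(cohort$endophenotypes$values), outs[4],
            rownames_as = "sample_id")
  write_tsv(cohort$endophenotypes$meta, outs[5])
  tr <- cohort$truth
  write_json_file(list(a = as.list(tr$a), b = as.list(tr$b), direct = tr$direct,
                       mediated_fraction = tr$mediated_fraction,
                       causal_snps = tr$causal_snps), outs[6])

  # feature-level acetylation data so the omics stage has real work:
  # each acetylation variable becomes a module of noisy copies
  acet <- cohort$endophenotypes$meta$variable[
    cohort$endophenotypes$meta$category == "acetylation-module"]
  with_stream(spec$seed, "features", {
    n <- nrow(cohort$endophenotypes$values)
    feats <- lapply(acet, function(v) {
      e <- cohort$endophenotypes$values[, v]
      sapply(seq_len(6), function(j) 0.9 * e + 0.3 * rnorm(n))
    })
    fm <- do.call(cbind, feats)
    colnames(fm) <- unlist(lapply(acet, function(v) sprintf("%s_f%d", v, 1:6)))
    rownames(fm) <- rownames(cohort$endophenotypes$values)
    write_tsv(as.data.frame(fm), outs[7], rownames_as = "sample_id")
    write_tsv(data.frame(feature = colnames(fm),
                         module = rep(acet, each = 6)), outs[8])
  })
  ann <- with_stream(spec$seed, "annotation",
                     synth_annotation(modules = acet))
  write_bed(ann$peaks_bed, outs[9])
  write_tsv(ann$peak_modules, outs[10])
  write_tsv(ann$genes, outs[11])
  writeLines(ann$gmt_lines, outs[12])

  write_stage_manifest(dir, "simulate", digest, character(0), outs,
                       list(n_individuals = spec$n_individuals,
                            n_snps = spec$n_snps, seed = spec$seed))
  list(skipped = FALSE, outputs = outs)
}

# toy genomic annotation for the enrichment stage: 60 genes on one synthetic
# chromosome, 6 gene sets of 10 genes, and peak sets per acetylation module
# with the first module's peaks planted inside the first term's domains
synth_annotation <- function(modules, n_genes = 60, n_bg_peaks = 260) {
  genes <- data.frame(
    gene = sprintf("gene%02d", seq_len(n_genes)), chr = 101L,
    tss = 100000L + (seq_len(n_genes) - 1L) * 50000L,
    strand = rep(c("+", "-"), length.out = n_genes),
    stringsAsFactors = FALSE
  )
  terms <- split(genes$gene, rep(seq_len(6), each = n_genes / 6))
  names(terms) <- sprintf("term%d", seq_len(6))
  gmt <- vapply(names(terms), function(t) {
    paste(c(t, "synthetic", terms[[t]]), collapse = "\t")
  }, character(1))

  peak_rows <- list()
  mk_peak <- function(id, mid) {
    data.frame(chr = 101L, start = mid - 250L, end = mid + 249L, label = id,
               stringsAsFactors = FALSE)
  }
  assigns <- list()
  pid <- 0L
  for (mi in seq_along(modules)) {
    n_mod <- 40L
    mids <- if (mi == 1L) {
      # planted: most peaks near term1 gene TSSs
      c(sample(genes$tss[genes$gene %in% terms$term1], 30, replace = TRUE) +
          sample(-2000:2000, 30, replace = TRUE),
        sample(100000:(100000 + n_genes * 50000), 10))
    } else {
      sample(100000:(100000 + n_genes * 50000), n_mod)
    }
    for (m in mids) {
      pid <- pid + 1L
      id <- sprintf("peak%04d", pid)
      peak_rows[[pid]] <- mk_peak(id, as.integer(m))
      assigns[[pid]] <- data.frame(peak = id, module = modules[mi],
                                   stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(n_bg_peaks)) {
    pid <- pid + 1L
    id <- sprintf("peak%04d", pid)
    peak_rows[[pid]] <- mk_peak(id, as.integer(
      sample(100000:(100000 + n_genes * 50000), 1)))
    assigns[[pid]] <- data.frame(peak = id, module = "background",
                                 stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peak_rows)
  list(peaks_bed = genomic_region(peaks$chr, peaks$start, peaks$end,
                                  peaks$label),
       peak_modules = do.call(rbind, assigns),
       genes = genes, gmt_lines = gmt)
}

stage_omics <- function(config, dir, digest) {
  ins <- c(pfile(dir, "endophenotypes.tsv"), pfile(dir, "endophenotype_meta.tsv"),
           pfile(dir, "features_acetyl.tsv"), pfile(dir, "modules_acetyl.tsv"))
  outs <- pfile(dir, "endophenotypes_assembled.tsv")
  if (stage_fresh(dir, "omics", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  endo <- read_tsv(ins[1])
  rownames(endo) <- endo$sample_id
  endo$sample_id <- NULL
  meta <- read_tsv(ins[2])
  feats <- read_tsv(ins[3])
  rownames(feats) <- feats$sample_id
  feats$sample_id <- NULL
  mods <- read_tsv(ins[4])

  eg <- eigengene(as.matrix(feats), mods, category = "acetylation-module")
  keep <- meta$variable[meta$category != "acetylation-module"]
  parts <- lapply(split(keep, meta$category[match(keep, meta$variable)]),
                  function(vars) {
    cat <- meta$category[match(vars[1], meta$variable)]
    as_endophenotypes(endo[, vars, drop = FALSE], cat)
  })
  assembled <- do.call(assemble_endophenotypes, c(parts, list(eg)))
  out_tab <- as.data.frame(assembled$values)
  write_tsv(out_tab, outs, rownames_as = "sample_id")
  write_tsv(assembled$meta, pfile(dir, "endophenotype_meta_assembled.tsv"))
  write_stage_manifest(dir, "omics", digest, ins,
                       c(outs, pfile(dir, "endophenotype_meta_assembled.tsv")),
                       list(n_variables = ncol(assembled$values)))
  list(skipped = FALSE, outputs = outs)
}

stage_motorscore <- function(config, dir, digest) {
  ins <- pfile(dir, "phenotypes.tsv")
  outs <- pfile(dir, "motor_scores.tsv")
  if (stage_fresh(dir, "motorscore", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  phen <- read_tsv(ins)
  sc <- score_motor(phen)
  sc <- cbind(data.frame(sample_id = phen$sample_id), sc)
  write_tsv(sc, outs)
  write_stage_manifest(dir, "motorscore", digest, ins, outs,
                       list(n = nrow(sc)))
  list(skipped = FALSE, outputs = outs)
}

stage_score <- function(config, dir, digest) {
  ins <- c(pfile(dir, "genotypes.vcf"), pfile(dir, "sumstats.tsv"))
  outs <- c(pfile(dir, "prs.tsv"), pfile(dir, "clumped.tsv"))
  if (stage_fresh(dir, "score", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  geno <- read_genotypes_vcf(ins[1])
  stats <- read_sumstats(ins[2])
  h <- harmonize(stats, geno)
  cl <- ld_clump(h, geno, config$clump_r2, config$clump_kb)
  prs <- compute_prs(cl, geno, config$thresholds)
  write_sumstats(cl, outs[2])
  tab <- data.frame(sample_id = prs$sample_ids)
  for (k in seq_along(prs$thresholds)) {
    tab[[sprintf("raw_%g", prs$thresholds[k])]] <- prs$raw[, k]
    tab[[sprintf("std_%g", prs$thresholds[k])]] <- prs$standardized[, k]
  }
  write_tsv(tab, outs[1])
  write_stage_manifest(dir, "score", digest, ins, outs,
                       list(n_snps_clumped = nrow(cl),
                            n_snps_used = as.list(prs$n_snps_used)))
  list(skipped = FALSE, outputs = outs)
}

read_prs_result <- function(path) {
  tab <- read_tsv(path)
  std_cols <- grep("^std_", names(tab), value = TRUE)
  thresholds <- as.numeric(sub("^std_", "", std_cols))
  raw <- as.matrix(tab[, sub("^std_", "raw_", std_cols), drop = FALSE])
  std <- as.matrix(tab[, std_cols, drop = FALSE])
  colnames(raw) <- colnames(std) <- as.character(thresholds)
  structure(list(raw = raw, standardized = std, thresholds = thresholds,
                 n_snps_used = setNames(rep(NA_integer_, length(thresholds)),
                                        as.character(thresholds)),
                 excluded = NULL, restricted_to = NULL, denominator = "snps",
                 sample_ids = tab$sample_id),
            class = "prs_result")
}

pipeline_covariates <- function(phen) {
  phen[, DEFAULT_COVARIATES, drop = FALSE]
}

stage_scan <- function(config, dir, digest) {
  ins <- c(pfile(dir, "prs.tsv"), pfile(dir, "motor_scores.tsv"),
           pfile(dir, "phenotypes.tsv"))
  outs <- pfile(dir, "scan.tsv")
  if (stage_fresh(dir, "scan", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  prs <- read_prs_result(ins[1])
  sc <- read_tsv(ins[2])
  phen <- read_tsv(ins[3])
  outcomes <- cbind(sc[, c("global_parkinsonism", "global_motor", "strength",
                           "dexterity", "gait")],
                    phen[, c("ad_dx", "pd_dx")])
  res <- prs_scan(prs, outcomes, pipeline_covariates(phen),
                  alpha = config$scan_alpha)
  write_tsv(res, outs)
  write_stage_manifest(dir, "scan", digest, ins, outs,
                       list(n_rows = nrow(res), alpha = config$scan_alpha))
  list(skipped = FALSE, outputs = outs)
}

stage_screen <- function(config, dir, digest) {
  ins <- c(pfile(dir, "endophenotypes_assembled.tsv"),
           pfile(dir, "endophenotype_meta_assembled.tsv"),
           pfile(dir, "motor_scores.tsv"), pfile(dir, "prs.tsv"),
           pfile(dir, "phenotypes.tsv"))
  outs <- c(pfile(dir, "screen_stage1.tsv"), pfile(dir, "screen_stage2.tsv"),
            pfile(dir, "screen_hits.tsv"))
  if (stage_fresh(dir, "screen", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  endo_tab <- read_tsv(ins[1])
  rownames(endo_tab) <- endo_tab$sample_id
  endo_tab$sample_id <- NULL
  meta <- read_tsv(ins[2])
  endos <- endophenotype_matrix(as.matrix(endo_tab), meta)
  sc <- read_tsv(ins[3])
  phen <- read_tsv(ins[5])
  prs <- read_prs_result(ins[4])
  outcomes <- sc[, c("global_parkinsonism", "dexterity")]
  res <- screen_endophenotypes(endos, outcomes,
                               prs_vector(prs, config$headline_threshold),
                               pipeline_covariates(phen),
                               alpha = config$screen_alpha)
  write_tsv(res$stage1, outs[1])
  if (!is.null(res$stage2)) write_tsv(res$stage2, outs[2]) else {
    write_tsv(data.frame(variable = character()), outs[2])
  }
  write_tsv(data.frame(variable = res$stage2_hits), outs[3])
  write_stage_manifest(dir, "screen", digest, ins, outs, res$thresholds)
  list(skipped = FALSE, outputs = outs)
}

stage_mediate <- function(config, dir, digest) {
  ins <- c(pfile(dir, "screen_hits.tsv"),
           pfile(dir, "endophenotypes_assembled.tsv"),
           pfile(dir, "motor_scores.tsv"), pfile(dir, "prs.tsv"),
           pfile(dir, "phenotypes.tsv"))
  outs <- pfile(dir, "mediation.tsv")
  if (stage_fresh(dir, "mediate", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  hits <- read_tsv(ins[1])$variable
  endo_tab <- read_tsv(ins[2])
  sc <- read_tsv(ins[3])
  prs <- prs_vector(read_prs_result(ins[4]), config$headline_threshold)
  phen <- read_tsv(ins[5])
  covs <- pipeline_covariates(phen)
  rows <- list()
  for (oc in c("global_parkinsonism", "dexterity")) {
    ry <- residualize(sc[[oc]], covs)
    use <- head(hits, 11L)
    if (!length(use)) next
    med <- mediate(ry, prs, endo_tab[, use, drop = FALSE], outcome_id = oc)
    tab <- med$per_endophenotype
    tab$outcome <- oc
    tab$joint <- med$joint
    rows[[oc]] <- tab
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(endophenotype = character())
  write_tsv(out, outs)
  write_stage_manifest(dir, "mediate", digest, ins, outs,
                       list(n_mediators = length(hits)))
  list(skipped = FALSE, outputs = outs)
}

stage_network <- function(config, dir, digest) {
  ins <- c(pfile(dir, "screen_hits.tsv"),
           pfile(dir, "endophenotypes_assembled.tsv"),
           pfile(dir, "motor_scores.tsv"), pfile(dir, "prs.tsv"),
           pfile(dir, "phenotypes.tsv"))
  outs <- c(pfile(dir, "network_edges.tsv"), pfile(dir, "network.dot"))
  if (stage_fresh(dir, "network", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  hits <- head(read_tsv(ins[1])$variable, 11L)
  endo_tab <- read_tsv(ins[2])
  sc <- read_tsv(ins[3])
  prs <- prs_vector(read_prs_result(ins[4]), config$headline_threshold)
  phen <- read_tsv(ins[5])
  covs <- pipeline_covariates(phen)
  ry <- residualize(sc$global_parkinsonism, covs)
  dat <- data.frame(prs = prs, endo_tab[, hits, drop = FALSE],
                    parkinsonism = ry, check.names = FALSE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  tiers <- tier_constraint(setNames(
    c("source", rep("intermediate", length(hits)), "sink"), names(dat)))
  net <- bootstrap_network(dat, tiers, n_boot = config$bn_boot,
                           seed = config$seed, threshold = config$bn_consensus,
                           restarts = config$bn_restarts)
  write_bnetwork(net, outs[1], outs[2])
  write_stage_manifest(dir, "network", digest, ins, outs,
                       list(n = nrow(dat), n_boot = config$bn_boot,
                            regulators = as.list(
                              direct_regulators(net, "parkinsonism"))))
  list(skipped = FALSE, outputs = outs)
}

stage_enrich <- function(config, dir, digest) {
  ins <- c(pfile(dir, "peaks.bed"), pfile(dir, "peak_modules.tsv"),
           pfile(dir, "genes.tsv"), pfile(dir, "genesets.gmt"))
  outs <- pfile(dir, "enrichment.tsv")
  if (stage_fresh(dir, "enrich", digest, ins, outs)) {
    return(list(skipped = TRUE, outputs = outs))
  }
  bed <- read_bed(ins[1])
  peaks <- data.frame(peak = bed$label, chr = bed$chr, start = bed$start,
                      end = bed$end, stringsAsFactors = FALSE)
  pm <- read_tsv(ins[2])
  genes <- read_tsv(ins[3])
  gs <- read_gmt(ins[4])
  domains <- regulatory_domains(genes)
  mapping <- assign_peaks(peaks, domains)
  rows <- list()
  for (mod in setdiff(unique(pm$module), "background")) {
    res <- test_enrichment(pm$peak[pm$module == mod], peaks$peak, mapping,
                           gs, fdr = config$fdr)
    if (nrow(res)) {
      res$module <- mod
      rows[[mod]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write_tsv(out, outs)
  write_stage_manifest(dir, "enrich", digest, ins, outs,
                       list(n_modules = length(rows), fdr = config$fdr))
  list(skipped = FALSE, outputs = outs)
}
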