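test_that("a lone gene gets basal plus maximal extension", {
  genes <- data.frame(gene = "g1", chr = 1, tss = 2e6, strand = "+")
  d <- regulatory_domains(genes, regdomain_rule(5000, 1000, 1e6))
  expect_equal(d$basal_start, 2e6 - 5000)
  expect_equal(d$basal_end, 2e6 + 1000)
  expect_equal(d$start, 2e6 - 5000 - 1e6)
  expect_equal(d$end, 2e6 + 1000 + 1e6)
})

test_that("neighboring genes' extensions abut at basal boundaries", {
  genes <- data.frame(gene = c("g1", "g2"), chr = 1, tss = c(1e6, 1e6 + 1e4),
                      strand = "+")
  d <- regulatory_domains(genes)
  # g1 extends right up to g2's basal start; g2 extends left to g1's basal end
  expect_equal(d$end[1], d$basal_start[2] - 1)
  expect_equal(d$start[2], d$basal_end[1] + 1)
})

test_that("minus-strand genes put the upstream extent on the higher-coordinate side", {
  genes <- data.frame(gene = "g1", chr = 1, tss = 5e6, strand = "-")
  d <- regulatory_domains(genes, regdomain_rule(5000, 1000, 1e6))
  expect_equal(d$basal_start, 5e6 - 1000)
  expect_equal(d$basal_end, 5e6 + 5000)
})

test_that("strand is mandatory", {
  expect_error(regulatory_domains(data.frame(gene = "g", chr = 1, tss = 1,
                                             strand = NA)), "strand")
})

test_that("peak midpoints map to one or several overlapping domains", {
  domains <- data.frame(gene = c("g1", "g2"), chr = 1,
                        start = c(100, 500), end = c(600, 900))
  peaks <- data.frame(peak = c("p1", "p2", "p3"), chr = 1,
                      start = c(180, 540, 950), end = c(220, 560, 960))
  mp <- assign_peaks(peaks, domains)
  expect_equal(mp$gene[mp$peak == "p1"], "g1")
  expect_setequal(mp$gene[mp$peak == "p2"], c("g1", "g2"))
  expect_false("p3" %in% mp$peak)
  expect_error(assign_peaks(data.frame(peak = "x", chr = 1, start = 10,
                                       end = 5), domains), "row 1")
})

test_that("peak assignment agrees with a brute-force interval scan", {
  for (s in 1:10) {
    set.seed(800 + s)
    n_dom <- 15
    domains <- data.frame(gene = sprintf("g%02d", 1:n_dom),
                          chr = sample(1:2, n_dom, TRUE),
                          start = sample(1:5000, n_dom))
    domains$end <- domains$start + sample(100:2000, n_dom)
    peaks <- data.frame(peak = sprintf("p%02d", 1:20),
                        chr = sample(1:2, 20, TRUE),
                        start = sample(1:6000, 20))
    peaks$end <- peaks$start + sample(10:500, 20)
    got <- assign_peaks(peaks, domains)
    mids <- floor((peaks$start + peaks$end) / 2)
    want <- list()
    for (i in 1:20) {
      for (j in 1:n_dom) {
        if (peaks$chr[i] == domains$chr[j] && mids[i] >= domains$start[j] &&
            mids[i] <= domains$end[j]) {
          want[[length(want) + 1]] <- paste(peaks$peak[i], domains$gene[j])
        }
      }
    }
    expect_setequal(paste(got$peak, got$gene), unlist(want))
  }
})

enrich_fixture <- function() {
  # universe of 20 genes, every peak maps to exactly one gene
  genes <- sprintf("g%02d", 1:20)
  mapping <- data.frame(peak = sprintf("p%02d", 1:20), gene = genes)
  list(all = mapping$peak, mapping = mapping, genes = genes)
}

test_that("hypergeometric tail matches exact combinatorial enumeration", {
  fx <- enrich_fixture()
  term <- fx$genes[1:5]
  module <- fx$all[c(1:4, 10, 11)]  # 4 of 5 term genes among 6 draws
  res <- test_enrichment(module, fx$all, fx$mapping, list(t = term),
                         method = "hypergeometric")
  # exact tail: sum over k >= 4 of C(5,k) C(15,6-k) / C(20,6)
  want <- sum(choose(5, 4:5) * choose(15, 2:1)) / choose(20, 6)
  expect_equal(res$p, want, tolerance = 1e-12)
  expect_equal(res$observed, 4)
  expect_equal(res$expected, 6 * 5 / 20)
  expect_equal(res$fold, 4 / (6 * 5 / 20))
})

test_that("a term covering the whole universe is unenriched by construction", {
  fx <- enrich_fixture()
  res <- test_enrichment(fx$all[1:6], fx$all, fx$mapping,
                         list(everything = fx$genes))
  expect_true(all(res$fold == 1))
  expect_true(all(res$p == 1))
})

test_that("duplicating every peak leaves the gene-based test unchanged", {
  fx <- enrich_fixture()
  term <- fx$genes[1:5]
  module <- fx$all[c(1:4, 10, 11)]
  base <- test_enrichment(module, fx$all, fx$mapping, list(t = term),
                          method = "hypergeometric")
  dup_map <- rbind(fx$mapping,
                   data.frame(peak = sprintf("q%02d", 1:20), gene = fx$genes))
  dup_all <- c(fx$all, sprintf("q%02d", 1:20))
  dup_module <- c(module, sub("^p", "q", module))
  dup <- test_enrichment(dup_module, dup_all, dup_map, list(t = term),
                         method = "hypergeometric")
  expect_equal(dup$p, base$p, tolerance = 1e-12)
})

test_that("binomial tail uses the all-peak hit fraction", {
  fx <- enrich_fixture()
  term <- fx$genes[1:5]   # 5 of 20 peaks hit the term: pi = 0.25
  module <- fx$all[c(1:4, 10, 11)]
  res <- test_enrichment(module, fx$all, fx$mapping, list(t = term),
                         method = "binomial")
  want <- pbinom(3, 6, 0.25, lower.tail = FALSE)
  expect_equal(res$p, want, tolerance = 1e-12)
})

test_that("empty terms are skipped with a warning and q-values are BH within method", {
  fx <- enrich_fixture()
  sets <- list(hit = fx$genes[1:5], off = c("zz1", "zz2"),
               other = fx$genes[6:10])
  expect_warning(
    res <- test_enrichment(fx$all[c(1:4, 10, 11)], fx$all, fx$mapping, sets),
    "off")
  expect_false("off" %in% res$term)
  # independent BH: hand formula p * m / rank, cumulative minimum from the top
  for (m in unique(res$method)) {
    sel <- res[res$method == m, ]
    p <- sel$p[order(sel$p)]
    q_hand <- rev(cummin(rev(p * length(p) / seq_along(p))))
    expect_equal(sort(sel$q), pmin(q_hand, 1), tolerance = 1e-12)
  }
})

test_that("module peaks must be a subset of all peaks", {
  fx <- enrich_fixture()
  expect_error(test_enrichment(c("nope"), fx$all, fx$mapping,
                               list(t = fx$genes[1:2])), "subset")
})
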