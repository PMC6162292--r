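stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run the full temporal-eQTL analysis pipeline
#'
#' Executes, in order: association scan, permutation FDR, hotspot detection,
#' cis/trans pairing at each hotspot, the pairwise causality test, and
#' regulator ranking. Artifacts are written under `config$out_dir`
#' (`scan.tsv`, `fdr.tsv`, `hotspots.bed`, `tgct.tsv`, `regulators.tsv`)
#' together with the configuration (`config.json`). All randomness derives
#' from `config$seed`; rerunning with the same configuration reproduces the
#' outputs exactly.
#'
#' @param config A [run_config()] (or path to its JSON form).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$expression, config$genotypes, config$marker_map,
              config$gene_map)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input path: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed %% .Machine$integer.max)

  expr <- read_expression(config$expression)
  geno <- read_genotypes(config$genotypes, config$marker_map)
  stage_log("load", "%d genes, %d strains, %d markers", length(expr),
            nrow(geno$genotypes), ncol(geno$genotypes))

  scan <- tryCatch(
    teqtl_scan(expr, geno$genotypes, method = config$method),
    error = function(e) stop("stage scan failed: ", conditionMessage(e)))
  utils::write.table(scan, file.path(config$out_dir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("scan", "method=%s records=%d", config$method, nrow(scan))

  fdr <- tryCatch(
    permutation_fdr(expr, geno$genotypes, method = config$method,
                    n_perm = config$n_perm, fdr_target = config$fdr_target,
                    scan = scan),
    error = function(e) stop("stage fdr failed: ", conditionMessage(e)))
  utils::write.table(fdr$table, file.path(config$out_dir, "fdr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log("fdr", "cutoff=%.3g at target %.2f", fdr$cutoff,
            config$fdr_target)
  if (is.na(fdr$cutoff)) stop("stage fdr failed: no cutoff reaches target")

  sig <- scan[scan$p.value <= fdr$cutoff, , drop = FALSE]
  hot <- tryCatch(
    detect_hotspots(sig, geno$map, bin_size = config$bin_size,
                    alpha = config$hotspot_alpha),
    error = function(e) stop("stage hotspots failed: ", conditionMessage(e)))
  write_hotspots_bed(hot$hotspots, file.path(config$out_dir, "hotspots.bed"))
  stage_log("hotspots", "%d hotspot(s), N0=%d", nrow(hot$hotspots), hot$n0)

  gene_map <- if (!is.null(config$gene_map))
    utils::read.delim(config$gene_map, stringsAsFactors = FALSE) else NULL
  calls_all <- list()
  regs_all <- list()
  if (!is.null(gene_map) && nrow(hot$hotspots)) {
    peaks <- peak_records(sig, geno$map)
    for (h in seq_len(nrow(hot$hotspots))) {
      hs <- hot$hotspots[h, ]
      in_hot <- peaks$chrom == hs$chrom & peaks$pos >= hs$start &
        peaks$pos < hs$end
      linked <- peaks[in_hot, , drop = FALSE]
      if (!nrow(linked)) next
      gm <- gene_map[match(linked$gene, gene_map$gene), ]
      is_cis <- !is.na(gm$chrom) & gm$chrom == hs$chrom &
        abs(gm$pos - (hs$start + hs$end) / 2) <= config$cis_window
      cis <- linked$gene[is_cis]
      trans <- linked$gene[!is_cis]
      if (!length(cis) || !length(trans)) next
      peak_marker <- linked$marker[which.min(linked$p.value)]
      calls <- tgct_pairs(expr, geno$genotypes[, peak_marker], cis, trans,
                          marker = peak_marker)
      regs <- rank_regulators(calls, hotspot_cutoff = hot$n0)
      regs$hotspot <- paste0(hs$chrom, ":", hs$start, "-", hs$end)
      calls_all[[length(calls_all) + 1L]] <- calls
      regs_all[[length(regs_all) + 1L]] <- regs
      stage_log("tgct", "hotspot %s: %d cis x %d trans, top=%s",
                regs$hotspot[1], length(cis), length(trans), regs$x_gene[1])
    }
  }
  calls <- if (length(calls_all)) do.call(rbind, calls_all) else NULL
  regs <- if (length(regs_all)) do.call(rbind, regs_all) else NULL
  if (!is.null(calls))
    utils::write.table(calls, file.path(config$out_dir, "tgct.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(regs))
    utils::write.table(regs, file.path(config$out_dir, "regulators.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(config, file.path(config$out_dir, "config.json"))
  invisible(list(scan = scan, fdr = fdr, hotspots = hot, calls = calls,
                 regulators = regs))
}
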