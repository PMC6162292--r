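#' Read a time-course expression matrix
#'
#' Accepts either the wide format (first column `strain`, remaining columns
#' named `gene@timepoint`) or the long format (columns `strain`, `gene`,
#' `time`, `value`). Missing cells are encoded `NA`. The time grid is
#' inferred from the column names (or `time` column) and sorted.
#'
#' @param path TSV file path.
#' @return Named list of `N x m` numeric matrices, one per gene, all with the
#'   same strain order; each carries a `"times"` attribute.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (all(c("strain", "gene", "time", "value") %in% names(d))) {
    if (anyDuplicated(d[c("strain", "gene", "time")]))
      stop("duplicate (strain, gene, time) rows")
    strains <- unique(d$strain)
    times <- sort(unique(d$time))
    out <- lapply(split(d, d$gene), function(dg) {
      m <- matrix(NA_real_, length(strains), length(times),
                  dimnames = list(strains, paste0("t", times)))
      m[cbind(match(dg$strain, strains), match(dg$time, times))] <- dg$value
      attr(m, "times") <- times
      m
    })
    return(out[order(names(out))])
  }
  if (names(d)[1] != "strain" || !all(grepl("@", names(d)[-1])))
    stop("expression TSV must be long (strain,gene,time,value) or wide ",
         "with 'strain' plus gene@timepoint columns")
  strains <- d[[1]]
  parts <- strsplit(names(d)[-1], "@", fixed = TRUE)
  genes <- vapply(parts, `[`, character(1), 1)
  tvals <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(tvals)) stop("non-numeric timepoint in a gene@timepoint header")
  vals <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values")
  out <- lapply(unique(genes), function(g) {
    sel <- which(genes == g)
    sel <- sel[order(tvals[sel])]
    m <- vals[, sel, drop = FALSE]
    dimnames(m) <- list(strains, paste0("t", tvals[sel]))
    attr(m, "times") <- tvals[sel]
    m
  })
  names(out) <- unique(genes)
  out
}

#' Write a time-course expression matrix collection (wide TSV)
#'
#' @param expression Named list of `N x m` matrices.
#' @param path Output TSV path.
#' @export
write_expression <- function(expression, path) {
  stopifnot(is.list(expression), length(expression) > 0)
  strains <- rownames(expression[[1]])
  if (is.null(strains)) strains <- paste0("s", seq_len(nrow(expression[[1]])))
  cols <- list(strain = strains)
  for (g in names(expression)) {
    m <- expression[[g]]
    times <- attr(m, "times")
    if (is.null(times)) times <- seq_len(ncol(m))
    for (j in seq_len(ncol(m))) cols[[paste0(g, "@", times[j])]] <- m[, j]
  }
  utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a genotype matrix and marker map
#'
#' @param path Genotype TSV: first column `strain`, remaining columns one per
#'   marker with codes 0/1 (haploid) or 0/1/2 (`diploid = TRUE`).
#' @param map_path Marker map TSV with columns `marker`, `chrom`, `pos`.
#' @param diploid Allow code 2.
#' @return List: `genotypes` (strains x markers integer matrix, columns
#'   sorted by map order), `map` (data.frame sorted by chrom then pos,
#'   stable for ties).
#' @export
read_genotypes <- function(path, map_path, diploid = FALSE) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (!file.exists(map_path)) stop("marker map not found: ", map_path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "strain") stop("genotype TSV must start with 'strain'")
  g <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- d$strain
  allowed <- if (diploid) 0:2 else 0:1
  bad <- setdiff(unique(as.vector(g)), allowed)
  if (length(bad))
    stop("unknown genotype code(s) ", paste(bad, collapse = ", "),
         if (!diploid && any(bad == 2)) " (did you mean diploid = TRUE?)")
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  if (!all(c("marker", "chrom", "pos") %in% names(map)))
    stop("marker map needs columns marker, chrom, pos")
  missing <- setdiff(colnames(g), map$marker)
  if (length(missing))
    stop("markers missing from map: ", paste(missing, collapse = ", "))
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  map <- map[map$marker %in% colnames(g), , drop = FALSE]
  rownames(map) <- NULL
  list(genotypes = g[, map$marker, drop = FALSE], map = map)
}

#' Write a genotype matrix
#' @param genotypes Strains x markers matrix.
#' @param path Output TSV path.
#' @export
write_genotypes <- function(genotypes, path) {
  strains <- rownames(genotypes)
  if (is.null(strains)) strains <- paste0("s", seq_len(nrow(genotypes)))
  utils::write.table(
    data.frame(strain = strains, genotypes, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a marker map
#' @param map Data.frame with `marker`, `chrom`, `pos`.
#' @param path Output TSV path.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map[, c("marker", "chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Write generating parameters of a simulated dataset (truth file)
#' @param truth A list of generating parameters.
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Write hotspot calls as BED
#' @param hotspots Data.frame with `chrom`, `start`, `end`, `count`, `n0`.
#' @param path Output BED path.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  utils::write.table(hotspots[, c("chrom", "start", "end", "count", "n0")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Run configuration for the analysis pipeline
#'
#' @param expression,genotypes,marker_map Input TSV paths.
#' @param gene_map Optional TSV path (`gene`, `chrom`, `pos`) locating genes,
#'   used for cis/trans pairing at hotspots.
#' @param out_dir Output directory.
#' @param method Association method for the scan.
#' @param fdr_target Target FDR for the scan cutoff.
#' @param n_perm Permutations for the FDR stage.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param bin_size Hotspot bin width (bp).
#' @param hotspot_alpha Hotspot binomial tail level.
#' @param filter_p Association filter for causality pairs.
#' @param cis_window Max gene-to-marker distance (bp) for a cis call.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, genotypes, marker_map, gene_map = NULL,
                       out_dir = ".", method = "mptga", fdr_target = 0.05,
                       n_perm = 10, seed = 1, bin_size = 20000,
                       hotspot_alpha = 0.05, filter_p = 1e-6,
                       cis_window = 50000) {
  structure(list(expression = expression, genotypes = genotypes,
                 marker_map = marker_map, gene_map = gene_map,
                 out_dir = out_dir, method = method,
                 fdr_target = fdr_target, n_perm = n_perm, seed = seed,
                 bin_size = bin_size, hotspot_alpha = hotspot_alpha,
                 filter_p = filter_p, cis_window = cis_window),
            class = "run_config")
}

#' Read or write a run configuration as JSON
#' @param path JSON path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}
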