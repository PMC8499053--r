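#' Score a collection of gene matrices against the mean-coverage baseline
#'
#' Convenience used by the simulation benchmark: computes `dT_nmf_mean`
#' (and, with `detail = TRUE`, the per-rank minima) for every matrix.
#'
#' @inheritParams score_gene
#' @param matrices named list of `odegr_matrix`.
#' @param verbose print a progress message every 50 genes.
#' @return data.frame `gene_id`, `T_nmf_pos`, `T_nmf_neg`, `T_mean`,
#'   `dT_nmf_mean` (+ `dT_mean_K<k>` columns when `detail`).
#' @export
score_matrices_mean <- function(matrices, labels, ranks = c(2L, 5L, 10L),
                                seeds = c(1L, 2L, 3L), detail = FALSE,
                                verbose = FALSE) {
  rows <- lapply(seq_along(matrices), function(i) {
    if (verbose && i %% 50 == 0)
      message(sprintf("  scored %d/%d genes", i, length(matrices)))
    r <- score_gene(matrices[[i]], NULL, labels, ranks = ranks,
                    seeds = seeds, detail = detail)
    row <- data.frame(gene_id = r$gene_id, T_nmf_pos = r$nmf_pair$t_pos,
                      T_nmf_neg = r$nmf_pair$t_neg, T_mean = r$t_mean,
                      dT_nmf_mean = r$delta_nmf_mean,
                      stringsAsFactors = FALSE)
    if (detail) {
      for (K in names(r$delta_mean_by_rank))
        row[[paste0("dT_mean_K", K)]] <- r$delta_mean_by_rank[[K]]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Local-DE simulation experiment: spike-in benchmark and AUROC
#'
#' Reproduces the simulation validation design: build positives by
#' grafting reshaped top-DE donors onto non-same-trend hosts at each
#' insert length, score positives and the unmodified negatives with the
#' multi-rank `dT_nmf_mean`, and measure how well the score separates the
#' two sets by AUROC. Negatives are scored once and shared across insert
#' lengths.
#'
#' @param matrices named list of raw `odegr_matrix` (e.g. from
#'   [synth_cohort()]).
#' @param labels an `odegr_labels`.
#' @param L_primes insert lengths in bins (default `c(100, 50, 10)`).
#' @param n_positives positives per insert length.
#' @param n_top donor pool size (default 100).
#' @param seed seed for benchmark construction.
#' @inheritParams score_gene
#' @param verbose progress messages.
#' @return list keyed by insert length, each with `auroc` (multi-rank
#'   score), `auroc_by_rank` (named by K), and `scores` (data.frame with
#'   `label` = 1 for positives).
#' @export
benchmark_experiment <- function(matrices, labels,
                                 L_primes = c(100L, 50L, 10L),
                                 n_positives = 150L, n_top = 100L,
                                 seed = 1L, ranks = c(2L, 5L, 10L),
                                 seeds = c(1L, 2L, 3L), verbose = FALSE) {
  if (verbose) message(sprintf("scoring %d negatives", length(matrices)))
  neg <- score_matrices_mean(matrices, labels, ranks, seeds, detail = TRUE,
                             verbose = verbose)
  neg$label <- 0L
  out <- list()
  for (Lp in L_primes) {
    if (verbose) message(sprintf("building %d positives at L' = %d",
                                 n_positives, Lp))
    bench <- generate_benchmark(matrices, labels, L_prime = Lp,
                                n_positives = n_positives, n_top = n_top,
                                seed = (seed * 131L + Lp) %%
                                  .Machine$integer.max)
    pos <- score_matrices_mean(bench$positives, labels, ranks, seeds,
                               detail = TRUE, verbose = verbose)
    pos$label <- 1L
    sc <- rbind(pos, neg)
    rank_cols <- grep("^dT_mean_K", colnames(sc), value = TRUE)
    out[[as.character(Lp)]] <- list(
      auroc = auroc(sc$dT_nmf_mean, sc$label),
      auroc_by_rank = setNames(
        vapply(rank_cols, function(cl) auroc(sc[[cl]], sc$label), numeric(1)),
        sub("^dT_mean_K", "", rank_cols)),
      scores = sc)
  }
  out
}

#' Desk-scale simulation study of local-DE detection
#'
#' The package's standard reproduction of the spike-in AUROC experiment:
#' a synthetic two-group cohort of 334 genes (60 + 60 cells, 300 bins,
#' 30% whole-gene DE at 0.5 log10 effect), top-100 whole-gene-DE donor
#' selection, 150 grafted positives per insert length, multi-rank
#' (K in 2, 5, 10) `dT_nmf_mean` scoring with three NMF seeds, AUROC per
#' insert length. The cohort size is chosen so the top-100 donor pool
#' consists of genuinely DE genes, mirroring the donor construction on
#' real data; 334 genes x 0.3 gives ~100 DE genes.
#'
#' @param seed master seed; drives the cohort, the benchmark draws and
#'   the NMF seed triple (`seed + 0:2`).
#' @param L_primes insert lengths (default `c(100, 50, 10)`).
#' @param n_genes,n_cells,n_bins,de_fraction,effect_log10 cohort
#'   parameters (defaults are the study conditions above).
#' @param n_positives,n_top benchmark parameters.
#' @param verbose progress messages.
#' @return as [benchmark_experiment()].
#' @export
simulation_study <- function(seed = 1L, L_primes = c(100L, 50L, 10L),
                             n_genes = 334L, n_cells = 60L, n_bins = 300L,
                             de_fraction = 0.3, effect_log10 = 0.5,
                             n_positives = 150L, n_top = 100L,
                             verbose = FALSE) {
  cohort <- synth_cohort(n_genes, n_cells, n_cells, n_bins,
                         de_fraction = de_fraction,
                         effect_log10 = effect_log10, seed = seed)
  benchmark_experiment(cohort$matrices, cohort$labels, L_primes = L_primes,
                       n_positives = n_positives, n_top = n_top,
                       seed = seed, seeds = seed + 0:2, verbose = verbose)
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  config
}

.need <- function(config, key) {
  if (is.null(config[[key]])) stop(sprintf("config key missing: %s", key))
  config[[key]]
}

.check_file <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s not found: %s", what, path))
  path
}

.read_labels_tsv <- function(path) {
  df <- read.delim(.check_file(path, "labels TSV"), stringsAsFactors = FALSE)
  group_labels(df[[1]], df[[2]])
}

#' Run the full coverage-to-ranking pipeline
#'
#' Reads the coverage manifest, GTF, TPM table and labels; selects
#' expressed transcripts and protein-coding genes; bins, masks, filters
#' and log-transforms each gene's coverage; scores every retained gene
#' (multi-rank NMF pairs vs TPM and mean references); ranks by
#' `dT_nmf_tpm` and writes the score TSV plus an attrition TSV recording
#' every dropped gene with its reason.
#'
#' @param config list or YAML file path with keys `coverage_manifest`
#'   (TSV: cell_id, path), `gtf`, `tpm`, `labels` (TSV: cell_id, group),
#'   optional `mappability`, `out` (output TSV), and optional parameters
#'   `bin_size` (100), `min_bins` (100), `mappability_floor` (0.5),
#'   `tpm_threshold` (0.5), `ranks` (2,5,10), `seeds` (1,2,3).
#' @return the ranked score data.frame, invisibly; written to `out` when
#'   set.
#' @export
run_score <- function(config) {
  cfg <- .load_config(config)
  bin_size <- cfg$bin_size %||% 100L
  min_bins <- cfg$min_bins %||% 100L
  floor_ <- cfg$mappability_floor %||% 0.5
  thr <- cfg$tpm_threshold %||% 0.5
  ranks <- as.integer(cfg$ranks %||% c(2L, 5L, 10L))
  seeds <- as.integer(cfg$seeds %||% c(1L, 2L, 3L))

  ann <- read_gtf_genes(.check_file(.need(cfg, "gtf"), "GTF"), bin_size)
  tpm <- read_tpm(.check_file(.need(cfg, "tpm"), "TPM TSV"),
                  ann$tx2gene, ann$gene_type)
  labels <- .read_labels_tsv(.need(cfg, "labels"))
  manifest <- read.delim(.check_file(.need(cfg, "coverage_manifest"),
                                     "coverage manifest"),
                         stringsAsFactors = FALSE)
  mapp <- if (!is.null(cfg$mappability))
    read_mappability(.check_file(cfg$mappability, "mappability track"))
  else {
    message("no mappability track supplied; mappability mask disabled")
    NULL
  }

  selected <- select_transcripts(tpm, thr)
  genes <- genes_from_transcripts(selected, tpm)
  genes <- intersect(genes, names(ann$regions))
  if (length(genes) == 0) stop("no gene passes the expression filters")
  message(sprintf("%d protein-coding genes pass the expression filter",
                  length(genes)))

  coverages <- lapply(manifest$path, read_coverage)
  names(coverages) <- manifest$cell_id

  mask_regions <- ann$regions[genes]
  attrition <- list()
  recs <- list()
  for (gid in genes) {
    region <- ann$regions[[gid]]
    raw <- build_gene_matrix(coverages, region)
    mask <- build_bin_mask(region, mask_regions, mapp,
                           mappability_floor = floor_)
    x <- finalize_gene_matrix(raw, mask, min_bins = min_bins)
    if (is.null(x)) {
      attrition[[gid]] <- data.frame(gene_id = gid, stage = "min_bins",
                                     reason = sprintf("%d kept bins < %d",
                                                      sum(mask), min_bins))
      next
    }
    rows <- gene_tpm_rows(tpm, gid, selected)
    if (nrow(rows) == 0) {
      attrition[[gid]] <- data.frame(gene_id = gid, stage = "tpm",
                                     reason = "no selected transcript")
      next
    }
    recs[[gid]] <- score_gene(x, rows, labels, ranks = ranks, seeds = seeds)
  }
  message(sprintf("scored %d genes; %d dropped", length(recs),
                  length(attrition)))
  if (length(recs) == 0) stop("no gene survives the bin filters")
  ranked <- rank_and_zscore(.records_to_df(recs), by = "dT_nmf_tpm")
  if (!is.null(cfg$out)) {
    write.table(ranked, cfg$out, sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(attrition) > 0)
      write.table(do.call(rbind, attrition),
                  paste0(cfg$out, ".attrition.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(ranked)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize a simulated benchmark on disk
#'
#' Generates a synthetic cohort ([synth_cohort()]) and a local-DE
#' benchmark ([generate_benchmark()]) and writes per-gene matrix TSVs, a
#' manifest, labels, the synthetic TPM table and the parameters to
#' `out_dir`.
#'
#' @param config list or YAML path; keys `out_dir`, `L_prime`, `seed`,
#'   `n_positives`, `n_top`, plus [synth_cohort()] parameters (`n_genes`,
#'   `n_cells_A`, `n_cells_B`, `n_bins`, `de_fraction`, `effect_log10`,
#'   `n_structures`, `dispersion`, `hidden_fraction`).
#' @return the benchmark object, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- .load_config(config)
  out_dir <- .need(cfg, "out_dir")
  L_prime <- as.integer(.need(cfg, "L_prime"))
  seed <- as.integer(cfg$seed %||% 1L)
  cohort <- synth_cohort(
    n_genes = as.integer(cfg$n_genes %||% 150L),
    n_cells_A = as.integer(cfg$n_cells_A %||% 60L),
    n_cells_B = as.integer(cfg$n_cells_B %||% 60L),
    n_bins = as.integer(cfg$n_bins %||% 300L),
    de_fraction = cfg$de_fraction %||% 0.3,
    effect_log10 = cfg$effect_log10 %||% 0.5,
    n_structures = as.integer(cfg$n_structures %||% 3L),
    dispersion = cfg$dispersion %||% 0.3,
    hidden_fraction = cfg$hidden_fraction %||% 0,
    seed = seed)
  bench <- generate_benchmark(cohort$matrices, cohort$labels, L_prime,
                              n_positives = as.integer(cfg$n_positives %||%
                                                         1000L),
                              n_top = as.integer(cfg$n_top %||% 100L),
                              seed = seed + 1L)
  write_benchmark(bench, out_dir, tpm = cohort$tpm)
  invisible(bench)
}

#' @rdname run_simulate
#' @param bench an `odegr_benchmark`.
#' @param out_dir output directory (created if absent).
#' @param tpm optional matched `odegr_tpm` to write alongside.
#' @export
write_benchmark <- function(bench, out_dir, tpm = NULL) {
  dir.create(file.path(out_dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  write_mat <- function(x, id) {
    df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE)
    colnames(df) <- c("cell_id", paste0("bin", seq_len(ncol(x$values))))
    write.table(df, file.path(out_dir, "matrices", paste0(id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (id in names(bench$negatives)) write_mat(bench$negatives[[id]], id)
  for (id in names(bench$positives)) write_mat(bench$positives[[id]], id)
  manifest <- data.frame(id = names(bench$negatives), label = "negative",
                         host = NA_character_, donor = NA_character_,
                         L_prime = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(bench$pos_meta) > 0) {
    manifest <- rbind(manifest, data.frame(
      id = bench$pos_meta$id, label = "positive",
      host = bench$pos_meta$host, donor = bench$pos_meta$donor,
      L_prime = bench$pos_meta$L_prime, stringsAsFactors = FALSE))
  }
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = names(bench$labels),
                         group = unclass(bench$labels)),
              file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(key = names(bench$params),
                         value = unlist(bench$params)),
              file.path(out_dir, "params.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(tpm)) {
    df <- data.frame(transcript_id = rownames(tpm$tpm), tpm$tpm,
                     check.names = FALSE)
    write.table(df, file.path(out_dir, "tpm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(out_dir)
}

#' Read a benchmark directory written by [write_benchmark()]
#'
#' @param dir benchmark directory.
#' @return list with `matrices` (all genes, named), `manifest`, `labels`,
#'   `params`.
#' @export
read_benchmark <- function(dir) {
  manifest <- read.delim(.check_file(file.path(dir, "manifest.tsv"),
                                     "benchmark manifest"),
                         stringsAsFactors = FALSE)
  labels <- .read_labels_tsv(file.path(dir, "labels.tsv"))
  params <- read.delim(file.path(dir, "params.tsv"),
                       stringsAsFactors = FALSE)
  matrices <- lapply(manifest$id, function(id) {
    df <- read.delim(file.path(dir, "matrices", paste0(id, ".tsv")),
                     check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    region <- gene_region(id, "chrS", 0L, ncol(vals) * 100L, "+", 100L)
    binned_region_matrix(region, vals, df[[1]])
  })
  names(matrices) <- manifest$id
  list(matrices = matrices, manifest = manifest, labels = labels,
       params = params)
}

#' Evaluate scores against a benchmark manifest
#'
#' @param config list or YAML path with keys `benchmark_dir`, `scores`
#'   (TSV as written by the scoring step, must contain every manifest
#'   gene), optional `out` (ROC points TSV prefix).
#' @return data.frame with one row per score column (`dT_nmf_mean`,
#'   `dT_nmf_tpm` where present): column name, AUROC, and the benchmark
#'   parameters.
#' @export
run_evaluate <- function(config) {
  cfg <- .load_config(config)
  dir <- .need(cfg, "benchmark_dir")
  manifest <- read.delim(.check_file(file.path(dir, "manifest.tsv"),
                                     "benchmark manifest"),
                         stringsAsFactors = FALSE)
  params <- read.delim(file.path(dir, "params.tsv"),
                       stringsAsFactors = FALSE)
  scores <- read.delim(.check_file(.need(cfg, "scores"), "score TSV"),
                       stringsAsFactors = FALSE)
  missing <- setdiff(manifest$id, scores$gene_id)
  if (length(missing) > 0)
    stop(sprintf("benchmark genes missing from scores: %s",
                 paste(utils::head(missing, 10), collapse = ", ")))
  scores <- scores[match(manifest$id, scores$gene_id), ]
  lab <- manifest$label == "positive"
  cols <- intersect(c("dT_nmf_mean", "dT_nmf_tpm"), colnames(scores))
  if (length(cols) == 0) stop("no delta score column found in scores")
  out <- do.call(rbind, lapply(cols, function(cl) {
    if (!is.null(cfg$out)) {
      write.table(roc_points(scores[[cl]], lab),
                  sprintf("%s.roc.%s.tsv", cfg$out, cl),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    data.frame(score = cl, auroc = auroc(scores[[cl]], lab),
               stringsAsFactors = FALSE)
  }))
  for (i in seq_len(nrow(params)))
    out[[params$key[i]]] <- params$value[i]
  out
}
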