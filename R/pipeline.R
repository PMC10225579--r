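#' Elements of one set absent from another
#'
#' Set difference `a \ b`, used to report condition-exclusive co-expressed
#' genes and hubs (e.g. members of case modules absent from control
#' modules).
#'
#' @param a,b Vectors.
#' @return Elements of `a` not in `b`.
#' @export
exclusive_elements <- function(a, b) setdiff(a, b)

#' Run the full differential co-expression pipeline
#'
#' Orchestrates every stage on a count matrix with two-condition labels:
#' preprocessing (optional biotype filter, global-average transcript filter,
#' sample depth filter), per-group co-expression analysis (each condition
#' plus the pooled samples), condition-exclusive gene and hub reporting,
#' the differential co-expression network over the union of module genes,
#' optional module/DCG stability, optional over-representation analysis and
#' optional cross-validated prediction. All randomness derives from one
#' seed via named per-stage sub-streams, so a rerun with the same inputs
#' and config reproduces identical outputs.
#'
#' @param counts Counts matrix (genes x samples) or path to a counts TSV.
#' @param condition Condition label per sample (two levels), or `NULL` if
#'   `metadata` is given.
#' @param metadata Optional data frame / TSV path with `sample_id`,
#'   `condition` (matched against `colnames(counts)`).
#' @param annotation Optional annotation data frame / TSV path
#'   (`gene_id`, `biotype`) enabling the biotype filter.
#' @param gmt Optional [read_gmt()] collection / GMT path enabling ORA of
#'   module genes and DCGs.
#' @param config Named list overriding defaults:
#'   `min_reads` (sample depth floor, default 1e7), `keep_biotypes`
#'   (default "protein_coding"), `filter_p` (inverse-gamma threshold, NULL
#'   to skip), `min_module_size`, `cut_height`, `n_hubs`, `betas`,
#'   `r2_target`, `rth`, `q_coexp`, `q_dcl`, `q_dcg`, `q_ora`, `method`,
#'   `diffcoexp_genes` (`"modules"`: the differential stage evaluates the
#'   genes assembled from either condition's co-expression modules, the
#'   default; `"all"`: every preprocessed gene),
#'   `coexpr_stability_reps` and `dcg_stability_reps` (0 disables the
#'   resampling stages), `stability_fraction` (default 0.7), `predict`
#'   (logical), `cv_rounds`, `cv_folds`.
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, every stage's tables are
#'   written (TSV/JSON) and their MD5 hashes recorded in the manifest.
#' @return Object of class `"pipeline_run"`: list with `results` (per-stage
#'   objects) and `manifest` (config snapshot, seed, per-file hashes,
#'   timestamps).
#' @export
run_pipeline <- function(counts, condition = NULL, metadata = NULL,
                         annotation = NULL, gmt = NULL, config = list(),
                         seed = 1L, out_dir = NULL) {
  defaults <- list(min_reads = 1e7, keep_biotypes = "protein_coding",
                   filter_p = 0.1, min_module_size = 30, cut_height = 0.99,
                   n_hubs = 5, betas = 1:20, r2_target = 0.8,
                   rth = 0.5, q_coexp = 0.1, q_dcl = 0.1, q_dcg = 0.1,
                   q_ora = 0.05, method = "pearson",
                   diffcoexp_genes = "modules",
                   coexpr_stability_reps = 0, dcg_stability_reps = 0,
                   stability_fraction = 0.7,
                   predict = TRUE, cv_rounds = 10, cv_folds = 5)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) stop("unknown config field(s): ", paste(unknown, collapse = ", "),
                                call. = FALSE)
  cfg <- utils::modifyList(defaults, config)

  if (is.character(counts)) counts <- read_counts_tsv(counts)
  check_counts(counts)
  if (is.null(condition)) {
    if (is.null(metadata)) stop("provide `condition` or `metadata`", call. = FALSE)
    if (is.character(metadata)) metadata <- read_metadata_tsv(metadata)
    condition <- metadata$condition[match(colnames(counts), metadata$sample_id)]
    if (anyNA(condition)) stop("metadata is missing sample(s) present in the counts", call. = FALSE)
  }
  condition <- check_condition(condition, counts)
  if (nlevels(condition) != 2) stop("the pipeline needs exactly two conditions", call. = FALSE)
  if (is.character(annotation)) annotation <- read_annotation_tsv(annotation)
  if (is.character(gmt)) gmt <- read_gmt(gmt)

  results <- list()
  t0 <- Sys.time()

  ## --- preprocess -------------------------------------------------------
  x <- counts
  if (!is.null(annotation)) x <- filter_by_biotype(x, annotation, keep = cfg$keep_biotypes)
  x <- filter_transcripts_global_average(x)
  n_before <- colnames(x)
  x <- filter_samples_by_depth(x, min_reads = cfg$min_reads)
  condition <- condition[match(colnames(x), n_before)]
  condition <- droplevels(condition)
  if (nlevels(condition) != 2) stop("a whole condition was removed by the depth filter", call. = FALSE)
  small <- table(condition) < 20
  if (any(small)) {
    warning("group(s) below the best-practice floor of 20 or more samples per group: ",
            paste(names(which(small)), collapse = ", "))
  }
  results$preprocess <- list(counts = x, condition = condition,
                             provenance = provenance(x))

  ## --- per-group co-expression -----------------------------------------
  groups <- list()
  lev <- levels(condition)
  groups[[lev[1]]] <- x[, condition == lev[1], drop = FALSE]
  groups[[lev[2]]] <- x[, condition == lev[2], drop = FALSE]
  groups[["pooled"]] <- x
  coexpr <- lapply(groups, function(g) {
    coexpression_analysis(g, filter_p = cfg$filter_p, betas = cfg$betas,
                          r2_target = cfg$r2_target,
                          min_module_size = cfg$min_module_size,
                          cut_height = cfg$cut_height, n_hubs = cfg$n_hubs,
                          method = cfg$method)
  })
  results$coexpression <- coexpr

  module_genes <- lapply(coexpr, function(r) {
    names(r$modules$module_of_gene)[r$modules$module_of_gene > 0]
  })
  hub_genes <- lapply(coexpr, function(r) unique(unlist(lapply(r$hubs, `[[`, "gene_id"))))
  results$exclusive <- list(
    genes = stats::setNames(
      list(exclusive_elements(module_genes[[lev[1]]], module_genes[[lev[2]]]),
           exclusive_elements(module_genes[[lev[2]]], module_genes[[lev[1]]])),
      lev),
    hubs = stats::setNames(
      list(exclusive_elements(hub_genes[[lev[1]]], hub_genes[[lev[2]]]),
           exclusive_elements(hub_genes[[lev[2]]], hub_genes[[lev[1]]])),
      lev))

  if (cfg$coexpr_stability_reps > 0) {
    results$module_stability <- module_stability(
      groups[[lev[2]]], sample_fraction = cfg$stability_fraction,
      n_reps = cfg$coexpr_stability_reps,
      seed = substream_seed(seed, "module-stability"),
      filter_p = cfg$filter_p, betas = cfg$betas, r2_target = cfg$r2_target,
      min_module_size = cfg$min_module_size, cut_height = cfg$cut_height,
      n_hubs = cfg$n_hubs, method = cfg$method)
  }

  ## --- differential co-expression --------------------------------------
  # "modules": the differential stage evaluates the genes assembled from the
  # co-expression modules of either condition; "all": every preprocessed gene
  dc_genes <- if (identical(cfg$diffcoexp_genes, "all")) {
    rownames(x)
  } else {
    sort(unique(c(module_genes[[lev[1]]], module_genes[[lev[2]]])))
  }
  if (length(dc_genes) < 2) {
    warning("fewer than 2 module genes across conditions; using all genes for ",
            "the differential stage")
    dc_genes <- rownames(x)
  }
  expr_all <- vst(x)
  cond_obj <- conditioned_expression(expr_all[dc_genes, , drop = FALSE], condition)
  network <- diffcoexp_network(cond_obj, rth = cfg$rth, q_coexp = cfg$q_coexp,
                               q_dcl = cfg$q_dcl, q_dcg = cfg$q_dcg,
                               method = cfg$method)
  results$diffcoexp <- network

  if (cfg$dcg_stability_reps > 0) {
    results$dcg_stability <- dcg_stability(
      cond_obj, sample_fraction = cfg$stability_fraction,
      n_reps = cfg$dcg_stability_reps,
      seed = substream_seed(seed, "dcg-stability"),
      rth = cfg$rth, q_coexp = cfg$q_coexp, q_dcl = cfg$q_dcl,
      q_dcg = cfg$q_dcg, method = cfg$method)
  }

  ## --- enrichment -------------------------------------------------------
  if (!is.null(gmt)) {
    universe <- coexpr[["pooled"]]$genes
    queries <- list()
    mog <- coexpr[[lev[2]]]$modules$module_of_gene
    for (l in seq_len(coexpr[[lev[2]]]$modules$n_modules)) {
      queries[[sprintf("%s_module_%d", lev[2], l)]] <- names(mog)[mog == l]
    }
    dcg_set <- network$dcgs$gene[network$dcgs$dcg]
    if (length(dcg_set) > 0) queries$dcgs <- dcg_set
    results$enrichment <- lapply(queries, function(q) {
      q <- intersect(q, universe)
      if (length(q) == 0) return(NULL)
      ora_hypergeom(q, universe, gmt, q_threshold = cfg$q_ora)
    })
  }

  ## --- prediction -------------------------------------------------------
  if (isTRUE(cfg$predict)) {
    feature_sets <- list(
      coexp_hubs = hub_genes[[lev[2]]],
      dcgs = network$dcgs$gene[network$dcgs$dcg],
      diffcoexp_network = network$nodes)
    feature_sets$dcgs_plus_hubs <- unique(c(feature_sets$dcgs, feature_sets$coexp_hubs))
    feature_sets <- Filter(function(g) length(g) > 0, feature_sets)
    enough <- min(table(condition)) >= cfg$cv_folds
    if (enough && length(feature_sets) > 0) {
      results$prediction <- lapply(names(feature_sets), function(nm) {
        cross_validated_boosting(expr_all, condition,
                                 list(name = nm, genes = feature_sets[[nm]]),
                                 rounds = cfg$cv_rounds, folds = cfg$cv_folds,
                                 seed = substream_seed(seed, paste0("predict-", nm)))
      })
      names(results$prediction) <- names(feature_sets)
    }
  }

  ## --- manifest ---------------------------------------------------------
  manifest <- list(config = cfg, seed = seed,
                   n_genes_in = nrow(counts), n_samples_in = ncol(counts),
                   n_genes_preprocessed = nrow(x), n_samples_preprocessed = ncol(x),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_pipeline_outputs(results, lev, out_dir)
    manifest$output_hashes <- as.list(tools::md5sum(files))
    names(manifest$output_hashes) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(results = results, manifest = manifest), class = "pipeline_run")
}

# Write the standard tabular outputs of a pipeline run; returns file paths.
write_pipeline_outputs <- function(results, lev, out_dir) {
  files <- character(0)
  add <- function(path) {
    files[[length(files) + 1]] <<- path
    path
  }
  for (g in names(results$coexpression)) {
    r <- results$coexpression[[g]]
    mod_df <- data.frame(gene_id = names(r$modules$module_of_gene),
                         module = unname(r$modules$module_of_gene))
    utils::write.table(mod_df, add(file.path(out_dir, sprintf("modules_%s.tsv", g))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hub_df <- do.call(rbind, lapply(names(r$hubs), function(l) {
      h <- r$hubs[[l]]
      if (nrow(h) == 0) return(NULL)
      data.frame(module = l, rank = seq_len(nrow(h)), gene_id = h$gene_id,
                 k_within = h$k_within)
    }))
    if (is.null(hub_df)) hub_df <- data.frame(module = character(0), rank = integer(0),
                                              gene_id = character(0), k_within = numeric(0))
    utils::write.table(hub_df, add(file.path(out_dir, sprintf("hubs_%s.tsv", g))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(r$soft_threshold)) {
      utils::write.table(r$soft_threshold$fit_table,
                         add(file.path(out_dir, sprintf("soft_threshold_%s.tsv", g))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  net <- results$diffcoexp
  dcl_cols <- intersect(c("gene_i", "gene_j", "r1", "p1", "r2", "p2", "z_stat",
                          "p_diff", "q_diff", "dcl_class"), names(net$dcls))
  utils::write.table(as.data.frame(net$dcls)[, dcl_cols],
                     add(file.path(out_dir, "dcls.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$dcgs, add(file.path(out_dir, "dcgs.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_json(net, add(file.path(out_dir, "network.json")))
  write_network_sif(net, add(file.path(out_dir, "network.sif")))
  for (side in lev) {
    writeLines(as.character(results$exclusive$genes[[side]]),
               add(file.path(out_dir, sprintf("exclusive_genes_%s.txt", side))))
    writeLines(as.character(results$exclusive$hubs[[side]]),
               add(file.path(out_dir, sprintf("exclusive_hubs_%s.txt", side))))
  }
  if (!is.null(results$dcg_stability)) {
    df <- data.frame(gene = names(results$dcg_stability),
                     recovery = unname(results$dcg_stability))
    utils::write.table(df, add(file.path(out_dir, "dcg_stability.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(results$enrichment)) {
    for (nm in names(results$enrichment)) {
      if (is.null(results$enrichment[[nm]])) next
      utils::write.table(as.data.frame(results$enrichment[[nm]]),
                         add(file.path(out_dir, sprintf("ora_%s.tsv", nm))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(results$prediction)) {
    pred_df <- do.call(rbind, lapply(results$prediction, function(p) {
      data.frame(feature_set = p$feature_set, n_features = p$n_features,
                 mean_auc = p$mean_auc, sd_auc = p$sd_auc,
                 mean_error = p$mean_error, sd_error = p$sd_error)
    }))
    utils::write.table(pred_df, add(file.path(out_dir, "prediction.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  unlist(files)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Differential co-expression pipeline run\n")
  cat(sprintf("  input: %d genes x %d samples; after preprocessing: %d x %d\n",
              x$manifest$n_genes_in, x$manifest$n_samples_in,
              x$manifest$n_genes_preprocessed, x$manifest$n_samples_preprocessed))
  for (g in names(x$results$coexpression)) {
    m <- x$results$coexpression[[g]]$modules
    cat(sprintf("  [%s] %d module(s)\n", g, m$n_modules))
  }
  print(x$results$diffcoexp)
  if (!is.null(x$results$prediction)) {
    for (p in x$results$prediction) {
      cat(sprintf("  prediction [%s]: mean AUC %.3f, mean error %.3f\n",
                  p$feature_set, p$mean_auc, p$mean_error))
    }
  }
  invisible(x)
}
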