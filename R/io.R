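#' Read a miRNA count matrix from TSV
#'
#' First column = miRNA ID, header row = specimen IDs, tab separated.
#' Duplicate IDs, negative or non-integer cells are rejected with
#' coordinates.
#'
#' @param path file path.
#' @return validated integer matrix (miRNA x specimen).
#' @export
read_counts <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate miRNA ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- raw[, -1, drop = FALSE]
  m <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  m <- matrix(m, nrow = nrow(vals),
              dimnames = list(ids, colnames(vals)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric cell at miRNA '%s', specimen '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix (miRNA x specimen).
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(mirna_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read the specimen metadata table
#'
#' CSV with required columns specimen_id and diagnosis (PDAC, CP or
#' healthy); optional columns metastasis, ca199_u_ml, cea_ng_ml, os_days,
#' os_event, cohort. Missing optional values stay NA and are never imputed.
#'
#' @param path file path.
#' @param counts optional count matrix; every specimen in it must appear
#'   in the metadata.
#' @return validated data.frame.
#' @export
read_metadata <- function(path, counts = NULL) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "diagnosis")
  if (!all(req %in% names(s)))
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  bad <- !s$diagnosis %in% c("PDAC", "CP", "healthy")
  if (any(bad))
    stop("unknown diagnosis value(s): ",
         paste(unique(s$diagnosis[bad]), collapse = ", "))
  if (anyDuplicated(s$specimen_id))
    stop("duplicate specimen_id in metadata")
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), s$specimen_id)
    if (length(miss))
      stop("specimen(s) in counts but not metadata: ",
           paste(miss, collapse = ", "))
  }
  for (col in c("metastasis", "ca199_u_ml", "cea_ng_ml", "os_days",
                "os_event", "cohort"))
    if (!col %in% names(s)) s[[col]] <- NA
  s
}

#' Write specimen metadata as CSV
#'
#' @param samples metadata data.frame.
#' @param path output path.
#' @export
write_metadata <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
}

#' Write the planted-truth sidecar of a simulated cohort as JSON
#'
#' @param truth `truth` element of an `ev_cohort`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Pipeline configuration
#'
#' @param thresholds diagnostic [filter_thresholds()].
#' @param ca199_threshold CA19-9 threshold (U/ml) of the combined rule.
#' @param cutoff_strategy how the ratio cutoff is set on the training
#'   cohort: "youden" (data-driven, default) or "fixed".
#' @param fixed_cutoff cutoff used when `cutoff_strategy = "fixed"`
#'   (default 0.06, the published diagnostic cutoff).
#' @param marker optional pre-specified [ratio_marker()]; when given,
#'   discovery is skipped and the marker is evaluated as-is.
#' @param bn_nodes number of miRNA nodes carried into the Bayesian network
#'   (top single-marker AUC candidates, padded with the most variable
#'   miRNAs); the three pathology nodes are added on top.
#' @param bn_max_iter,bn_tabu_len,bn_patience tabu-search controls.
#' @param do_bn,do_survival stage switches.
#' @param met_thresholds [filter_thresholds()] for the metastasis analysis.
#' @param seed integer seed recorded with the run.
#' @param out_dir optional directory; each stage writes its tables there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = filter_thresholds(),
                            ca199_threshold = 300,
                            cutoff_strategy = c("youden", "fixed"),
                            fixed_cutoff = 0.06,
                            marker = NULL,
                            bn_nodes = 20, bn_max_iter = 2000,
                            bn_tabu_len = 10, bn_patience = 10,
                            do_bn = TRUE, do_survival = TRUE,
                            met_thresholds = filter_thresholds(),
                            seed = 1L, out_dir = NULL) {
  structure(list(thresholds = thresholds,
                 ca199_threshold = ca199_threshold,
                 cutoff_strategy = match.arg(cutoff_strategy),
                 fixed_cutoff = fixed_cutoff, marker = marker,
                 bn_nodes = bn_nodes, bn_max_iter = bn_max_iter,
                 bn_tabu_len = bn_tabu_len, bn_patience = bn_patience,
                 do_bn = do_bn, do_survival = do_survival,
                 met_thresholds = met_thresholds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, out_dir, name) {
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}

ratio_of <- function(norm, num, den) {
  x <- norm_values(norm)
  v <- x[num, ] / x[den, ]
  v[x[den, ] == 0] <- NA
  v
}

#' Run the full diagnostic / network / survival pipeline
#'
#' Chains normalization, differential candidate filtering, single-marker
#' and ratio-marker discovery with cutoff selection on the training
#' specimens, frozen-rule evaluation on the test specimens (ratio rule and
#' combined rule with serum CA19-9), Bayesian-network learning with
#' cause/consequence extraction around the `cancer` node, and the
#' metastasis/survival subgroup analysis. Discovery sees training
#' specimens only; the `cohort` metadata column ("training"/"test")
#' controls the split, and with no split column all specimens train and
#' are also evaluated (logged).
#'
#' @param counts raw count matrix (miRNA x specimen).
#' @param samples metadata as from [read_metadata()].
#' @param config a [pipeline_config()].
#' @return list of class `ev_report` with per-stage outputs.
#' @export
run_pipeline <- function(counts, samples, config = pipeline_config()) {
  if (is.null(samples) || nrow(samples) == 0L)
    stop("[metadata] empty metadata table")
  stage <- "input"
  out <- list(config = config)
  tryCatch({
    validate_counts(counts)
    miss <- setdiff(colnames(counts), samples$specimen_id)
    if (length(miss))
      stop("specimen(s) in counts but not metadata: ",
           paste(miss, collapse = ", "))
    samples <- samples[match(colnames(counts), samples$specimen_id), ]
    if (!"cohort" %in% names(samples) || all(is.na(samples$cohort))) {
      stage_log("input", "no cohort column: all specimens train and evaluate")
      samples$cohort <- "training"
    }
    train_ids <- samples$specimen_id[samples$cohort == "training"]
    test_ids <- samples$specimen_id[samples$cohort == "test"]

    stage <- "normalize"
    norm_tr <- normalize_counts(counts[, train_ids, drop = FALSE])
    stage_log(stage, "training: %d specimens, %d housekeeping miRNAs",
              length(train_ids), length(norm_tr$housekeeping_ids))
    norm_te <- NULL
    if (length(test_ids) >= 2L) {
      norm_te <- normalize_counts(counts[, test_ids, drop = FALSE])
      stage_log(stage, "test: %d specimens, %d housekeeping miRNAs",
                length(test_ids), length(norm_te$housekeeping_ids))
    }
    out$normalized <- list(training = norm_tr, test = norm_te)
    lab_tr <- samples$diagnosis[match(train_ids, samples$specimen_id)]
    lab_te <- samples$diagnosis[match(test_ids, samples$specimen_id)]

    if (is.null(config$marker)) {
      stage <- "diffexpr"
      de <- de_table(counts[, train_ids, drop = FALSE], norm_tr, lab_tr,
                     "PDAC", "CP")
      write_tsv(de, config$out_dir, "de_training.tsv")
      cand <- candidate_filter(de, config$thresholds, mode = "diagnostic")
      # denominator pool: highly and differentially expressed, no
      # fold-change clause (the pair search screens quotients, not levels)
      pool <- candidate_filter(de, config$thresholds, mode = "metastatic")
      stage_log(stage, "%d diagnostic candidates; %d in the ratio pool",
                length(cand), length(pool))
      out$de <- de; out$candidates <- cand; out$ratio_pool <- pool
      if (length(cand) < 1L || length(pool) < 2L)
        stop("too few candidates; cannot search ratio pairs")

      stage <- "biomarker"
      singles <- rank_single_markers(norm_tr, lab_tr, cand, case = "PDAC")
      write_tsv(singles, config$out_dir, "single_markers_training.tsv")
      numerator <- singles$mirna_id[1]
      ratios <- ratio_search(norm_tr, lab_tr, numerator, pool,
                             case = "PDAC")
      write_tsv(ratios, config$out_dir, "ratio_search_training.tsv")
      denominator <- ratios$denominator[1]
      rv_tr <- ratio_of(norm_tr, numerator, denominator)
      keep <- !is.na(rv_tr) & lab_tr %in% c("PDAC", "CP")
      cutoff <- if (config$cutoff_strategy == "fixed") config$fixed_cutoff
        else choose_cutoff(rv_tr[keep], lab_tr[keep], "youden",
                           case = "PDAC")
      marker <- ratio_marker(numerator, denominator, cutoff,
                             auc = ratios$auc[1],
                             roc_points = roc_curve(rv_tr[keep],
                                                    lab_tr[keep], "PDAC"))
      stage_log(stage, "ratio %s/%s: training AUC %.3f, cutoff %.4g",
                numerator, denominator, marker$auc, cutoff)
      out$single_markers <- singles; out$ratio_search <- ratios
    } else {
      marker <- config$marker
      stage_log("biomarker", "evaluation-only mode: using supplied %s/%s",
                marker$numerator_id, marker$denominator_id)
    }
    out$marker <- marker

    stage <- "classify"
    rule <- combined_rule(marker$cutoff, config$ca199_threshold)
    out$rule <- rule
    eval_cohort <- function(norm, ids) {
      if (is.null(norm)) return(NULL)
      sub <- samples[match(ids, samples$specimen_id), ]
      keep <- sub$diagnosis %in% c("PDAC", "CP")
      x <- ratio_of(norm, marker$numerator_id, marker$denominator_id)[keep]
      y <- sub$ca199_u_ml[keep]
      truth <- sub$diagnosis[keep]
      ok <- !is.na(x)
      list(calls = data.frame(specimen_id = sub$specimen_id[keep][ok],
                              x = x[ok], y = y[ok],
                              ratio_call = classify_ratio(x[ok],
                                                          marker$cutoff),
                              combined_call = classify_combined(x[ok],
                                                                y[ok], rule),
                              truth = truth[ok],
                              stringsAsFactors = FALSE),
           auc = auc(x[ok], truth[ok], case = "PDAC"))
    }
    ev_tr <- eval_cohort(norm_tr, train_ids)
    ev_te <- eval_cohort(norm_te, test_ids)
    conf <- function(ev, col)
      if (is.null(ev)) NULL else
        confusion_metrics(ev$calls[[col]], ev$calls$truth)
    out$evaluation <- list(
      training = list(calls = ev_tr$calls, auc = ev_tr$auc,
                      ratio = conf(ev_tr, "ratio_call"),
                      combined = conf(ev_tr, "combined_call")),
      test = if (is.null(ev_te)) NULL else
        list(calls = ev_te$calls, auc = ev_te$auc,
             ratio = conf(ev_te, "ratio_call"),
             combined = conf(ev_te, "combined_call")))
    if (!is.null(config$out_dir)) {
      write_tsv(ev_tr$calls, config$out_dir, "calls_training.tsv")
      if (!is.null(ev_te)) write_tsv(ev_te$calls, config$out_dir,
                                     "calls_test.tsv")
    }

    if (config$do_bn) {
      stage <- "bayesnet"
      pool <- if (!is.null(out$single_markers))
        out$single_markers$mirna_id else
          c(marker$numerator_id, marker$denominator_id)
      vr <- apply(norm_tr$values, 1, stats::var)
      pool <- unique(c(pool,
                       rownames(norm_tr$values)[order(-vr)]))
      pool <- utils::head(pool, config$bn_nodes)
      disc <- discretize_by_median(norm_tr$values[pool, , drop = FALSE])
      disc <- add_pathology_nodes(disc, samples)
      dag <- tabu_search(disc, max_iter = config$bn_max_iter,
                         tabu_len = config$bn_tabu_len,
                         patience = config$bn_patience,
                         seed = config$seed)
      nb <- neighborhood(dag, "cancer")
      stage_log(stage, "%d nodes, %d edges, score %.2f; cancer: %d %s",
                length(dag$nodes), nrow(dag_edges(dag)), dag$score,
                length(nb$causes) + length(nb$consequences),
                "causes+consequences")
      write_tsv(dag_edges(dag), config$out_dir, "bn_edges.tsv")
      out$bn <- list(dag = dag, cancer_neighborhood = nb)
    }

    if (config$do_survival && any(samples$os_event %in% c(0, 1))) {
      stage <- "survival"
      met <- metastasis_candidates(counts[, train_ids, drop = FALSE],
                                   norm_tr,
                                   samples[match(train_ids,
                                                 samples$specimen_id), ],
                                   thresholds = config$met_thresholds)
      out$metastasis <- met
      if (!is.null(met$best_pair)) {
        mp <- met$best_pair
        # pooled-cohort survival stratification at the frozen cutoff
        all_norm <- cbind(norm_tr$values,
                          if (!is.null(norm_te)) norm_te$values)
        pdac <- samples$diagnosis == "PDAC" & !is.na(samples$os_days)
        ids <- intersect(samples$specimen_id[pdac], colnames(all_norm))
        rv <- all_norm[mp$numerator_id, ids] / all_norm[mp$denominator_id,
                                                        ids]
        grp <- stratify_by_ratio(rv, mp$cutoff)
        rec <- data.frame(specimen_id = ids,
                          os_days = samples$os_days[match(ids,
                                                samples$specimen_id)],
                          os_event = samples$os_event[match(ids,
                                                samples$specimen_id)],
                          group = grp, stringsAsFactors = FALSE)
        if (length(unique(grp)) == 2L && any(rec$os_event == 1)) {
          lr <- logrank_test(rec)
          km <- lapply(split(rec, rec$group), km_estimate)
          stage_log(stage,
                    "ratio %s/%s > %.3g: log-rank p = %.3g (%d patients)",
                    mp$numerator_id, mp$denominator_id, mp$cutoff,
                    lr$p_value, nrow(rec))
          out$survival <- list(records = rec, logrank = lr, km = km)
        }
      }
    }
    class(out) <- "ev_report"
    out
  }, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' @export
print.ev_report <- function(x, ...) {
  cat("Blood small-EV miRNA pipeline report\n")
  if (!is.null(x$marker))
    cat(sprintf("  ratio marker: %s / %s (cutoff %.4g, training AUC %.3f)\n",
                x$marker$numerator_id, x$marker$denominator_id,
                x$marker$cutoff, x$marker$auc))
  for (coh in c("training", "test")) {
    ev <- x$evaluation[[coh]]
    if (is.null(ev)) next
    cat(sprintf("  %s cohort (ratio AUC %.3f):\n", coh, ev$auc))
    cat(sprintf("    ratio rule:    sens %.1f%%  spec %.1f%%\n",
                ev$ratio$sensitivity, ev$ratio$specificity))
    cat(sprintf("    combined rule: sens %.1f%%  spec %.1f%%\n",
                ev$combined$sensitivity, ev$combined$specificity))
  }
  if (!is.null(x$bn))
    cat(sprintf("  Bayesian network: %d nodes, %d edges; cancer has %d causes, %d consequences\n",
                length(x$bn$dag$nodes), nrow(dag_edges(x$bn$dag)),
                length(x$bn$cancer_neighborhood$causes),
                length(x$bn$cancer_neighborhood$consequences)))
  if (!is.null(x$survival))
    cat(sprintf("  survival: log-rank p = %.3g over %d PDAC patients\n",
                x$survival$logrank$p_value, nrow(x$survival$records)))
  invisible(x)
}
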