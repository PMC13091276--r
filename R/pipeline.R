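# End-to-end orchestration: synthetic cohort (or files) -> preprocessing ->
# diversity -> enterotype -> succinotype -> differential abundance ->
# per-group and per-succinotype networks -> network statistics, with a
# manifest of every output and deterministic stage seeds derived from the
# master seed.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] to simulate the cohort, or `NULL` when
#'   `inputs` is given.
#' @param inputs named list of file paths (`bacterial`, `fungal`,
#'   `bact_taxonomy`, `fungal_taxonomy`, `metadata`).
#' @param rare_asv_fraction rare-taxon cutoff (default 0.001).
#' @param da_prevalence differential-abundance prevalence filter (0.10).
#' @param network_prevalence network prevalence filter (0.20).
#' @param rarefy_quantile rarefaction depth as a quantile of sample
#'   depths (default 0.1: the 10th percentile, retaining ~90% of samples).
#' @param k_range DMM component counts to try.
#' @param dmm_restarts EM restarts per K.
#' @param succinotype_hi,succinotype_lo,succinotype_min_reads
#'   classification thresholds (0.9 / 0.1 / 10).
#' @param stars_subsample,stars_reps,stars_beta StARS parameters
#'   (0.8 / 50 / 0.05).
#' @param leiden_resolution community resolution (0.5).
#' @param keystone_fraction keystone cutoff (0.05).
#' @param n_perm PERMANOVA permutations.
#' @param seed master seed; every stage derives its own stream from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(), inputs = NULL,
                            rare_asv_fraction = 0.001,
                            da_prevalence = 0.10, network_prevalence = 0.20,
                            rarefy_quantile = 0.1,
                            k_range = 1:3, dmm_restarts = 3,
                            succinotype_hi = 0.9, succinotype_lo = 0.1,
                            succinotype_min_reads = 10,
                            stars_subsample = 0.8, stars_reps = 50,
                            stars_beta = 0.05,
                            leiden_resolution = 0.5, keystone_fraction = 0.05,
                            n_perm = 999, seed = 1L) {
  stopifnot(rare_asv_fraction > 0, rare_asv_fraction < 1,
            da_prevalence >= 0, da_prevalence < 1,
            network_prevalence >= 0, network_prevalence < 1,
            succinotype_lo < succinotype_hi)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

load_inputs <- function(config) {
  if (!is.null(config$inputs)) {
    ip <- config$inputs
    list(bacterial = read_count_table(ip$bacterial),
         fungal = read_count_table(ip$fungal),
         bact_taxonomy = read_taxonomy_table(ip$bact_taxonomy),
         fungal_taxonomy = read_taxonomy_table(ip$fungal_taxonomy),
         metadata = read_sample_metadata(ip$metadata),
         truth = NULL)
  } else {
    sc <- config$synth
    sc$seed <- stage_seed(config$seed, "synthgen")
    generate_cohort(sc)
  }
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic or file-based cohort and (when
#' `out_dir` is given) writes all tables, networks and a manifest JSON
#' with file checksums and stage seeds. Identical config and seed give a
#' byte-identical output bundle.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return the result bundle (list), invisibly when writing.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- load_inputs(config)
  miss <- setdiff(data$bacterial$sample_id, data$metadata$sample_id)
  if (length(miss))
    abort(paste0("metadata missing sample present in counts: ", miss[1]))

  # preprocess: rare-taxon filter, genus aggregation, rarefaction
  seed_pre <- stage_seed(config$seed, "preprocess")
  bact <- rare_asv_filter(data$bacterial, config$rare_asv_fraction)
  fung <- rare_asv_filter(data$fungal, config$rare_asv_fraction)
  bact_g <- aggregate_by_rank(bact, data$bact_taxonomy, "genus")
  fung_g <- aggregate_by_rank(fung, data$fungal_taxonomy, "genus")
  depth_b <- floor(stats::quantile(rowSums(count_matrix(bact_g)), config$rarefy_quantile))
  depth_f <- floor(stats::quantile(rowSums(count_matrix(fung_g)), config$rarefy_quantile))
  bact_r <- rarefy_counts(bact_g, depth_b, seed_pre)
  fung_r <- rarefy_counts(fung_g, depth_f, seed_pre + 1L)

  # diversity
  seed_div <- stage_seed(config$seed, "diversity")
  alpha <- alpha_diversity(bact_r)
  bray <- beta_distance(bact_r, "bray_curtis")
  jac <- beta_distance(bact_r, "jaccard")
  meta_r <- data$metadata[data$metadata$sample_id %in% bact_r$sample_id, ]
  meta_r$blastocystis_pos <- meta_r$blastocystis != "neg"
  pv <- dplyr::bind_rows(
    permanova(bray, meta_r, "group", n_perm = config$n_perm, seed = seed_div) |>
      dplyr::mutate(metric = "bray_curtis"),
    permanova(jac, meta_r, "group", n_perm = config$n_perm, seed = seed_div + 1L) |>
      dplyr::mutate(metric = "jaccard"),
    permanova(bray, meta_r, "calprotectin", covariates = "group",
              n_perm = config$n_perm, seed = seed_div + 2L) |>
      dplyr::mutate(metric = "bray_curtis"),
    permanova(bray, meta_r, "blastocystis_pos", covariates = "group",
              n_perm = config$n_perm, seed = seed_div + 3L) |>
      dplyr::mutate(metric = "bray_curtis"))
  pw <- pairwise_permanova(bray, meta_r, "group", n_perm = config$n_perm,
                           seed = seed_div + 10L)

  # enterotype
  seed_ent <- stage_seed(config$seed, "enterotype")
  sel <- select_k(bact_r, k_range = config$k_range,
                  n_restarts = config$dmm_restarts, seed = seed_ent)
  best_fit <- sel$fits[[paste0("k", sel$best["bic"])]]
  ent <- assign_enterotypes(best_fit)
  contrib <- if (sel$best["bic"] > 1 && "k1" %in% names(sel$fits))
    genus_contributions(best_fit, sel$fits[["k1"]]) else NULL

  # succinotype (unrarefied genus counts keep the read-depth exclusion rule)
  calls <- classify_cohort(bact_g, data$bact_taxonomy,
                           hi = config$succinotype_hi, lo = config$succinotype_lo,
                           min_reads = config$succinotype_min_reads)
  prev <- succinotype_prevalence(calls, data$metadata)
  assoc <- association_tests(calls, data$metadata, c("group", "calprotectin"))

  # differential abundance + fungal dysbiosis ratio
  da <- da_screen(bact_g, data$metadata, grouping = "group",
                  prevalence = config$da_prevalence)
  da_cal <- da_screen(bact_g, data$metadata, grouping = "group",
                      strata = "calprotectin", prevalence = config$da_prevalence)
  ba <- ba_ratio(fung_g, data$fungal_taxonomy)

  # networks: cross-domain per group, bacterial-only per succinotype
  seed_net <- stage_seed(config$seed, "network")
  net_of <- function(tbls, sd) {
    infer_network(tbls, prevalence = config$network_prevalence,
                  subsample_fraction = config$stars_subsample,
                  n_reps = config$stars_reps, beta = config$stars_beta,
                  seed = sd)
  }
  groups <- sort(unique(data$metadata$group))
  group_nets <- stats::setNames(purrr::imap(groups, function(g, i) {
    ids <- data$metadata$sample_id[data$metadata$group == g]
    net_of(list(bacterial = bact_g[bact_g$sample_id %in% ids, ],
                fungal = fung_g[fung_g$sample_id %in% ids, ]),
           seed_net + i)
  }), groups)
  succ_labels <- intersect(c("D", "P", "mixed"), unique(calls$label))
  succ_nets <- stats::setNames(purrr::imap(succ_labels, function(s, i) {
    ids <- calls$sample_id[calls$label == s]
    if (length(ids) < 5) return(NULL)
    net_of(list(bacterial = bact_g[bact_g$sample_id %in% ids, ]),
           seed_net + 100L + i)
  }), succ_labels)
  succ_nets <- succ_nets[!vapply(succ_nets, is.null, logical(1))]

  seed_ns <- stage_seed(config$seed, "netstats")
  reports <- purrr::imap(c(group_nets, succ_nets), function(nt, nm)
    network_report(nt, resolution = config$leiden_resolution,
                   top_fraction = config$keystone_fraction, seed = seed_ns))

  bundle <- list(config = config, data = data,
                 preprocessed = list(bacterial = bact_g, fungal = fung_g,
                                     bacterial_rarefied = bact_r,
                                     fungal_rarefied = fung_r,
                                     rarefy_depths = c(bacterial = depth_b,
                                                       fungal = depth_f)),
                 diversity = list(alpha = alpha, permanova = pv, pairwise = pw),
                 enterotype = list(selection = sel, assignments = ent,
                                   contributions = contrib),
                 succinotype = list(calls = calls, prevalence = prev,
                                    associations = assoc),
                 abundance = list(da = da, da_calprotectin = da_cal, ba_ratio = ba),
                 networks = list(group = group_nets, succinotype = succ_nets),
                 reports = reports)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  files <- c(
    wt(bundle$preprocessed$bacterial_rarefied, "bacterial_rarefied.tsv"),
    wt(bundle$diversity$alpha, "alpha_diversity.tsv"),
    wt(bundle$diversity$permanova, "permanova.tsv"),
    wt(bundle$diversity$pairwise, "pairwise_permanova.tsv"),
    wt(bundle$enterotype$selection$scores, "dmm_scores.tsv"),
    wt(bundle$enterotype$assignments, "enterotype_labels.tsv"),
    wt(bundle$succinotype$calls, "succinotype_calls.tsv"),
    wt(bundle$succinotype$prevalence, "succinotype_prevalence.tsv"),
    wt(bundle$succinotype$associations, "succinotype_associations.tsv"),
    wt(bundle$abundance$da, "differential_abundance.tsv"),
    wt(bundle$abundance$ba_ratio, "ba_ratio.tsv"))
  if (!is.null(bundle$enterotype$contributions))
    files <- c(files, wt(bundle$enterotype$contributions, "genus_contributions.tsv"))
  nets <- c(bundle$networks$group, bundle$networks$succinotype)
  kinds <- c(rep("group", length(bundle$networks$group)),
             rep("succinotype", length(bundle$networks$succinotype)))
  for (i in seq_along(nets)) {
    base <- paste0("network_", kinds[i], "_", names(nets)[i])
    write_edge_list(nets[[i]], file.path(out_dir, paste0(base, "_edges.tsv")))
    rp <- bundle$reports[[names(nets)[i]]]
    write_network_report(rp, file.path(out_dir, base), net = nets[[i]])
    files <- c(files, paste0(base, c("_edges.tsv", "_global.json", "_nodes.tsv",
                                     "_robustness.tsv", "_viz.graphml")))
  }
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    seed = bundle$config$seed,
    stage_seeds = list(synthgen = stage_seed(bundle$config$seed, "synthgen"),
                       preprocess = stage_seed(bundle$config$seed, "preprocess"),
                       diversity = stage_seed(bundle$config$seed, "diversity"),
                       enterotype = stage_seed(bundle$config$seed, "enterotype"),
                       network = stage_seed(bundle$config$seed, "network"),
                       netstats = stage_seed(bundle$config$seed, "netstats")),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Human-readable pipeline summary
#'
#' One plain-text document summarizing enterotype selection, succinotype
#' prevalences (both normalizations), the PERMANOVA R^2 table,
#' differential-abundance hit counts, and per-network metrics with
#' keystones and robustness indices. Regeneration is idempotent.
#'
#' @param bundle result of [run_pipeline()].
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly when writing.
#' @export
make_report <- function(bundle, path = NULL) {
  l <- character(0)
  add <- function(...) l <<- c(l, paste0(...))
  add("== Cohort ==")
  add("samples: ", nrow(bundle$data$metadata), " (",
      paste(names(table(bundle$data$metadata$group)),
            table(bundle$data$metadata$group), sep = "=", collapse = ", "), ")")
  add("")
  add("== Enterotypes (DMM) ==")
  sc <- bundle$enterotype$selection
  add("K tried: ", paste(sc$scores$k, collapse = ", "),
      "; best by BIC: ", sc$best["bic"], ", AIC: ", sc$best["aic"],
      ", Laplace: ", sc$best["laplace"])
  tab <- table(bundle$enterotype$assignments$enterotype)
  add("assignments: ", paste(names(tab), tab, sep = "=", collapse = ", "))
  add("")
  add("== Succinotypes ==")
  pv <- bundle$succinotype$prevalence
  coh <- pv |> dplyr::group_by(.data$label) |>
    dplyr::summarise(n = sum(.data$n), prop = sum(.data$prop_cohort))
  for (i in seq_len(nrow(coh)))
    add(coh$label[i], ": n=", coh$n[i], " cohort fraction=",
        sprintf("%.2f", coh$prop[i]))
  add("(within-group fractions in succinotype_prevalence.tsv)")
  add("")
  add("== PERMANOVA (R^2 x 100%) ==")
  pvv <- bundle$diversity$permanova
  keep <- !pvv$term %in% c("Residual", "Total") & pvv$focal
  for (i in which(keep))
    add(pvv$metric[i], " ", pvv$term[i], ": R2=",
        sprintf("%.1f%%", 100 * pvv$R2[i]), " p=", format(pvv$p[i]),
        " [", pvv$adjustment[i], "]")
  add("")
  add("== Differential abundance (Wilcoxon/BH) ==")
  da <- bundle$abundance$da
  if (nrow(da) == 0) add("0 genera tested") else {
    hits <- da |> dplyr::filter(.data$p_adj < 0.05) |>
      dplyr::count(.data$level1, .data$level2)
    comps <- da |> dplyr::distinct(.data$level1, .data$level2)
    for (i in seq_len(nrow(comps))) {
      h <- hits$n[hits$level1 == comps$level1[i] & hits$level2 == comps$level2[i]]
      add(comps$level1[i], " vs ", comps$level2[i], ": ",
          if (length(h)) h else 0, " genera at FDR 0.05")
    }
  }
  add("")
  add("== Networks ==")
  for (nm in names(bundle$reports)) {
    rp <- bundle$reports[[nm]]
    g <- rp$global
    ksn <- if (nrow(rp$keystones) && "is_keystone" %in% names(rp$keystones))
      rp$keystones$node[rp$keystones$is_keystone] else character(0)
    add(nm, ": nodes=", g$n_nodes, " edges=", g$n_edges,
        " (+", g$n_positive, "/-", g$n_negative, ")",
        " modularity=", sprintf("%.3f", g$modularity),
        " transitivity=", sprintf("%.3f", g$transitivity))
    if (!is.null(rp$robustness_targeted))
      add("  targeted attack: AUC=", sprintf("%.3f", rp$robustness_targeted$auc),
          " R50=", sprintf("%.3f", rp$robustness_targeted$r50))
    if (length(ksn)) add("  keystones: ", paste(ksn, collapse = ", "))
  }
  if (!is.null(path)) { writeLines(l, path); return(invisible(l)) }
  l
}
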