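# Seeded synthetic-cohort generator. Emulates the statistical structure the
# downstream stages assume: a four-group cohort (9/29/31/30), two
# Bacteroides-dominant enterotype mixtures, succinotype structure through
# Dialister/Phascolarctobacterium read ratios, a fungal table carrying the
# Basidiomycota/Ascomycota phylum split, and bacterial counts whose latent
# log-abundances follow a known sparse precision matrix (the network
# ground truth).

#' Synthetic cohort configuration
#'
#' Defaults encode the cohort structure the package's analyses expect:
#' group sizes 9/29/31/30 (control/IBS/UC/CD), two genus-level enterotype
#' mixture components, succinotype target prevalences 43% D / 30% P /
#' 18% mixed / 9% unclassified, and desk-scale sequencing depths
#' (lognormal, median 5000 reads for bacteria and 3000 for fungi).
#'
#' @param group_sizes named integer vector of samples per group.
#' @param n_bact_taxa,n_fungal_taxa number of genera per kingdom.
#' @param bact_depth,fungal_depth lognormal depth parameters
#'   `c(meanlog, sdlog)`.
#' @param enterotype_alphas list of two positive Dirichlet parameter
#'   vectors over bacterial genera (`NULL` = built-in profiles).
#' @param enterotype_weights mixing proportions (simplex).
#' @param succinotype_targets named fractions for D/P/mixed/unclassified,
#'   summing to 1.
#' @param network_topology `"band"`, `"cluster"` or `"scale_free"`.
#' @param network_strength partial-correlation magnitude of true edges.
#' @param calprotectin_enterotype_odds odds multiplier linking
#'   calprotectin positivity to enterotype 2 (1 = independence).
#' @param seed integer RNG seed.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(group_sizes = c(control = 9L, IBS = 29L, UC = 31L, CD = 30L),
                         n_bact_taxa = 250L,
                         n_fungal_taxa = 150L,
                         bact_depth = c(meanlog = log(5000), sdlog = 0.35),
                         fungal_depth = c(meanlog = log(3000), sdlog = 0.35),
                         enterotype_alphas = NULL,
                         enterotype_weights = c(0.5, 0.5),
                         succinotype_targets = c(D = 0.43, P = 0.30,
                                                 mixed = 0.18, unclassified = 0.09),
                         network_topology = c("band", "cluster", "scale_free"),
                         network_strength = 0.3,
                         calprotectin_enterotype_odds = 1,
                         seed = 1L) {
  network_topology <- match.arg(network_topology)
  if (any(group_sizes < 0)) abort("group_sizes must be non-negative")
  if (abs(sum(succinotype_targets) - 1) > 1e-9 || any(succinotype_targets < 0))
    abort("succinotype_targets must be non-negative and sum to 1")
  if (abs(sum(enterotype_weights) - 1) > 1e-9 || any(enterotype_weights < 0))
    abort("enterotype_weights must lie on the simplex")
  if (n_bact_taxa < 10 || n_fungal_taxa < 5) abort("too few taxa requested")
  cfg <- list(group_sizes = group_sizes, n_bact_taxa = as.integer(n_bact_taxa),
              n_fungal_taxa = as.integer(n_fungal_taxa),
              bact_depth = bact_depth, fungal_depth = fungal_depth,
              enterotype_alphas = enterotype_alphas,
              enterotype_weights = enterotype_weights,
              succinotype_targets = succinotype_targets,
              network_topology = network_topology,
              network_strength = network_strength,
              calprotectin_enterotype_odds = calprotectin_enterotype_odds,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Read a synthetic-cohort configuration from a YAML file
#' @param path YAML file with `synth_config` fields.
#' @return a validated `synth_config`.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$group_sizes)) y$group_sizes <- unlist(y$group_sizes)
  if (!is.null(y$succinotype_targets)) y$succinotype_targets <- unlist(y$succinotype_targets)
  if (!is.null(y$enterotype_weights)) y$enterotype_weights <- unlist(y$enterotype_weights)
  if (!is.null(y$bact_depth)) y$bact_depth <- unlist(y$bact_depth)
  if (!is.null(y$fungal_depth)) y$fungal_depth <- unlist(y$fungal_depth)
  do.call(synth_config, y)
}

bact_genus_names <- function(p) {
  named <- c("Bacteroides", "Faecalibacterium", "Escherichia_Shigella",
             "Streptococcus", "Alistipes", "Akkermansia", "Segatella",
             "Bifidobacterium", "Dialister", "Phascolarctobacterium")
  c(named, sprintf("BactGenus%03d", seq_len(p - length(named))))
}

fungal_genus_names <- function(p) {
  named <- c("Rigidoporus", "Malassezia", "Saitozyma", "Candida",
             "Meyerozyma", "Didymella")
  c(named, sprintf("FungGenus%03d", seq_len(p - length(named))))
}

# Two Bacteroides-dominant component alpha vectors with a heavy-tailed
# abundance decay; component 2 is enriched 10-fold in Escherichia_Shigella
# and Streptococcus and depleted in Faecalibacterium/Alistipes.
default_enterotype_alphas <- function(p) {
  base <- 1 / (seq_len(p))^1.3
  names(base) <- bact_genus_names(p)
  a1 <- base
  a2 <- base
  a2[c("Escherichia_Shigella", "Streptococcus")] <-
    a2[c("Escherichia_Shigella", "Streptococcus")] * 10
  a2[c("Faecalibacterium", "Alistipes")] <-
    a2[c("Faecalibacterium", "Alistipes")] / 10
  scale_to <- 60  # total concentration: strong interindividual overdispersion
  list(a1 / sum(a1) * scale_to, a2 / sum(a2) * scale_to)
}

#' Draw counts from a Dirichlet-multinomial mixture
#'
#' Each row i draws a component `z_i ~ Categorical(weights)`, a composition
#' `p_i ~ Dirichlet(alphas[[z_i]])`, then `multinomial(depths[i], p_i)`.
#'
#' @param alphas list of strictly positive Dirichlet parameter vectors.
#' @param weights mixing proportions (same length as `alphas`).
#' @param n number of samples.
#' @param depths per-sample totals (recycled to length `n`).
#' @param seed optional RNG seed.
#' @return list with `counts` (count tibble) and `labels` (integer vector).
#' @export
sample_dmm_counts <- function(alphas, weights, n, depths, seed = NULL) {
  if (!is.list(alphas)) alphas <- list(alphas)
  if (any(vapply(alphas, function(a) any(a <= 0), logical(1))))
    abort("all Dirichlet parameters must be strictly positive")
  if (length(weights) != length(alphas)) abort("weights must match alphas")
  depths <- rep_len(depths, n)
  draw <- function() {
    z <- sample.int(length(alphas), n, replace = TRUE, prob = weights)
    p <- length(alphas[[1]])
    counts <- matrix(0, n, p)
    for (i in seq_len(n)) {
      g <- stats::rgamma(p, shape = alphas[[z[i]]])
      counts[i, ] <- as.vector(stats::rmultinom(1, depths[i], g / sum(g)))
    }
    colnames(counts) <- names(alphas[[1]]) %||% paste0("T", seq_len(p))
    rownames(counts) <- sprintf("S%03d", seq_len(n))
    list(counts = as_count_tbl(counts), labels = z)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a sparse symmetric positive-definite precision matrix
#'
#' Off-diagonal support follows the requested topology: `band` connects
#' |i-j| = 1 neighbours, `cluster` is block-diagonal (blocks of 5),
#' `scale_free` is a preferential-attachment tree. Edge entries alternate
#' in sign with magnitude `strength`; the diagonal is inflated if needed
#' so the minimum eigenvalue stays positive.
#'
#' @param topology `"band"`, `"cluster"` or `"scale_free"`.
#' @param p dimension (>= 3).
#' @param strength off-diagonal magnitude (default 0.3).
#' @param seed RNG seed (used only by `scale_free`).
#' @return p x p precision matrix with attribute `"adjacency"`.
#' @export
make_precision_matrix <- function(topology = c("band", "cluster", "scale_free"),
                                  p, strength = 0.3, seed = 1L) {
  topology <- match.arg(topology)
  if (p < 3) abort("p must be at least 3")
  omega <- diag(p)
  edges <- switch(topology,
    band = cbind(seq_len(p - 1), seq_len(p - 1) + 1L),
    cluster = {
      blocks <- split(seq_len(p), (seq_len(p) - 1) %/% 5)
      do.call(rbind, lapply(blocks, function(b) {
        if (length(b) < 2) return(NULL)
        t(utils::combn(b, 2))
      }))
    },
    scale_free = {
      g <- with_seed(seed, igraph::sample_pa(p, power = 1, m = 1, directed = FALSE))
      igraph::as_edgelist(g, names = FALSE)
    })
  sgn <- rep_len(c(-1, 1), nrow(edges))  # mixed positive/negative partial correlations
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    omega[i, j] <- omega[j, i] <- sgn[k] * strength
  }
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-3) {
    omega <- omega + diag(1e-3 - ev, p)
    message("precision diagonal inflated by ", signif(1e-3 - ev, 3),
            " to restore positive definiteness")
  }
  adj <- matrix(0L, p, p)
  adj[edges] <- 1L
  adj <- adj + t(adj)
  attr(omega, "adjacency") <- adj
  omega
}

#' Draw counts with a known latent precision structure
#'
#' Logistic-normal-multinomial sampler: latent log-abundances are
#' multivariate normal with the supplied precision (plus an optional base
#' log-mean profile), softmax-composed and multinomially sampled.
#'
#' @param precision SPD precision matrix.
#' @param n number of samples.
#' @param depths per-sample totals (recycled).
#' @param base_logmean optional latent mean vector (default 0).
#' @param seed optional RNG seed.
#' @return count tibble.
#' @export
sample_network_counts <- function(precision, n, depths, base_logmean = NULL, seed = NULL) {
  p <- ncol(precision)
  depths <- rep_len(depths, n)
  base <- base_logmean %||% rep(0, p)
  draw <- function() {
    R <- chol(precision)            # z = R^{-1} e  has covariance precision^{-1}
    counts <- matrix(0, n, p)
    for (i in seq_len(n)) {
      z <- backsolve(R, stats::rnorm(p))
      prob <- exp(base + z - max(base + z))
      counts[i, ] <- as.vector(stats::rmultinom(1, depths[i], prob / sum(prob)))
    }
    colnames(counts) <- colnames(precision) %||% paste0("T", seq_len(p))
    rownames(counts) <- sprintf("S%03d", seq_len(n))
    as_count_tbl(counts)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Draw (nD, nP) pairs that realise a requested succinotype label under the
# rD > 0.9 / rD < 0.1 / total >= 10 rule.
draw_succinotype_counts <- function(label) {
  switch(label,
    D = { nP <- stats::rpois(1, 2); nD <- max(9L * nP + 1L + stats::rpois(1, 60), 10L); c(nD, nP) },
    P = { nD <- stats::rpois(1, 2); nP <- max(9L * nD + 1L + stats::rpois(1, 60), 10L); c(nD, nP) },
    mixed = {
      total <- 10L + stats::rpois(1, 80)
      lo <- ceiling(0.1 * total); hi <- floor(0.9 * total)
      nD <- round(stats::runif(1, 0.2, 0.8) * total)
      nD <- min(max(nD, lo), hi)
      c(nD, total - nD)
    },
    unclassified = { total <- sample(0:9, 1); nD <- stats::rbinom(1, total, 0.5); c(nD, total - nD) })
}

#' Generate a full synthetic cohort
#'
#' Produces genus-level bacterial and fungal count tables, taxonomy tables,
#' sample metadata, and a ground-truth record (enterotype labels,
#' succinotype classes, generating alphas and the true network adjacency).
#' Bacterial counts follow a two-component logistic-normal-multinomial: the
#' latent log-mean comes from the sample's enterotype component profile and
#' the latent covariance from a known sparse precision matrix, so the same
#' cohort carries both enterotype and association-network ground truth.
#' Succinate-utilizer genus columns (Dialister, Phascolarctobacterium) are
#' then drawn per sample from the target succinotype class.
#'
#' @param config a [synth_config()].
#' @return list with `bacterial`, `fungal` (count tibbles), `bact_taxonomy`,
#'   `fungal_taxonomy`, `metadata`, and `truth`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- sum(config$group_sizes)
    ids <- sprintf("S%03d", seq_len(n))
    group <- rep(names(config$group_sizes), config$group_sizes)

    alphas <- config$enterotype_alphas %||% default_enterotype_alphas(config$n_bact_taxa)
    p_b <- config$n_bact_taxa
    omega <- make_precision_matrix(config$network_topology, p_b,
                                   config$network_strength, seed = config$seed)
    ent <- sample.int(2, n, replace = TRUE, prob = config$enterotype_weights)
    depths_b <- pmax(200L, round(stats::rlnorm(n, config$bact_depth[1], config$bact_depth[2])))
    R <- chol(omega)
    bact <- matrix(0, n, p_b, dimnames = list(ids, names(alphas[[1]])))
    for (i in seq_len(n)) {
      base <- log(alphas[[ent[i]]] / sum(alphas[[ent[i]]]))
      z <- backsolve(R, stats::rnorm(p_b))
      pr <- exp(base + z - max(base + z))
      bact[i, ] <- stats::rmultinom(1, depths_b[i], pr / sum(pr))
    }

    succ <- sample(names(config$succinotype_targets), n, replace = TRUE,
                   prob = config$succinotype_targets)
    for (i in seq_len(n)) {
      dp <- draw_succinotype_counts(succ[i])
      bact[i, "Dialister"] <- dp[1]
      bact[i, "Phascolarctobacterium"] <- dp[2]
    }

    # Fungal table: single heavy-tailed Dirichlet component; phyla assigned
    # so the expected Basidiomycota/Ascomycota mass ratio is about 2.
    p_f <- config$n_fungal_taxa
    fa <- 1 / seq_len(p_f)^1.3
    names(fa) <- fungal_genus_names(p_f)
    fa <- fa / sum(fa) * 40
    depths_f <- pmax(200L, round(stats::rlnorm(n, config$fungal_depth[1], config$fungal_depth[2])))
    fung <- matrix(0, n, p_f, dimnames = list(ids, names(fa)))
    for (i in seq_len(n)) {
      g <- stats::rgamma(p_f, shape = fa)
      fung[i, ] <- stats::rmultinom(1, depths_f[i], g / sum(g))
    }
    basidio <- c("Rigidoporus", "Malassezia", "Saitozyma")
    fung_phylum <- ifelse(names(fa) %in% basidio |
                            (seq_len(p_f) > 6 & seq_len(p_f) %% 3 == 0),
                          "Basidiomycota", "Ascomycota")

    age_med <- c(control = 41, IBS = 36, UC = 30, CD = 24)[group]
    age <- pmax(18, round(age_med + stats::rnorm(n, 0, 8)))
    calpro_p <- c(control = 0.10, IBS = 0.25, UC = 0.72, CD = 0.60)[group]
    if (config$calprotectin_enterotype_odds != 1) {
      odds <- calpro_p / (1 - calpro_p)
      odds[ent == 2] <- odds[ent == 2] * config$calprotectin_enterotype_odds
      calpro_p <- odds / (1 + odds)
    }
    calprotectin <- ifelse(stats::runif(n) < calpro_p, "pos", "neg")
    sym <- function(p_by_group) stats::runif(n) < p_by_group[group]
    blasto_p <- c(control = 0.78, IBS = 0.55, UC = 0.45, CD = 0.37)[group]
    blasto <- ifelse(stats::runif(n) < blasto_p,
                     sample(c("ST1", "ST3", "other"), n, replace = TRUE,
                            prob = c(0.77, 0.22, 0.01)),
                     "neg")
    metadata <- tibble::tibble(
      sample_id = ids, group = group, age = age, calprotectin = calprotectin,
      abdominal_pain = sym(c(control = 0.2, IBS = 0.79, UC = 0.5, CD = 0.5)),
      nausea = sym(c(control = 0.15, IBS = 0.38, UC = 0.2, CD = 0.2)),
      vomiting = sym(c(control = 0.44, IBS = 0.15, UC = 0.15, CD = 0.15)),
      diarrhoea = sym(c(control = 0.2, IBS = 0.5, UC = 0.6, CD = 0.55)),
      anorexia = sym(c(control = 0.1, IBS = 0.2, UC = 0.3, CD = 0.35)),
      bloating = sym(c(control = 0.2, IBS = 0.6, UC = 0.3, CD = 0.3)),
      urgency = sym(c(control = 0.1, IBS = 0.4, UC = 0.5, CD = 0.4)),
      blastocystis = blasto)

    bact_tax <- tibble::tibble(
      taxon_id = colnames(bact), kingdom = "Bacteria",
      phylum = ifelse(colnames(bact) %in% c("Bacteroides", "Alistipes", "Segatella"),
                      "Bacteroidota", "Bacillota"),
      genus = colnames(bact))
    fung_tax <- tibble::tibble(
      taxon_id = colnames(fung), kingdom = "Fungi",
      phylum = fung_phylum, genus = colnames(fung))

    list(bacterial = as_count_tbl(bact),
         fungal = as_count_tbl(fung),
         bact_taxonomy = bact_tax,
         fungal_taxonomy = fung_tax,
         metadata = metadata,
         truth = list(enterotype = stats::setNames(ent, ids),
                      succinotype = stats::setNames(succ, ids),
                      alphas = alphas,
                      precision = omega,
                      adjacency = attr(omega, "adjacency")))
  })
}

#' Write a synthetic cohort to a directory
#'
#' Emits tab-separated count/taxonomy/metadata tables plus a ground-truth
#' JSON file.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(cohort$bacterial, file.path(dir, "bacterial_counts.tsv"))
  write_count_table(cohort$fungal, file.path(dir, "fungal_counts.tsv"))
  write_taxonomy_table(cohort$bact_taxonomy, file.path(dir, "bact_taxonomy.tsv"))
  write_taxonomy_table(cohort$fungal_taxonomy, file.path(dir, "fungal_taxonomy.tsv"))
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- cohort$truth
  truth$precision <- NULL
  truth$adjacency <- which(cohort$truth$adjacency == 1, arr.ind = TRUE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
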