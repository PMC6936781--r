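#' Run the full analysis pipeline
#'
#' Orchestrates diversity -> ordination/PERMANOVA -> flavor PCA/HCA ->
#' O2PLS/VIP -> correlation networks -> core screen from a single config,
#' writing every stage artifact, a JSON report and a manifest into a run
#' directory. Re-running with the same config and seed reproduces all
#' outputs bit-identically (timestamps only appear in the log).
#'
#' The config is a list (or path to a YAML file) with exactly one of:
#' * `inputs`: list with `abundance`, `flavor` (TSV paths) and optional
#'   `annotation`;
#' * `simulate`: arguments for [simulate_dataset()].
#'
#' Further keys (all optional, defaults in parentheses): `metric`
#' (`"bray_curtis"`; or `"hellinger"`), `n_perm` (999), `o2pls` — a list
#' with either fixed `K`, `nx`, `ny` or ranges `K_range`, `nx_range`,
#' `ny_range` for cross-validated selection —, `correlation` (list:
#' `method` `"pearson"`, `thresholds` `c(0.7, 0.8)`), `screen` (list:
#' `vip_cut` 1.0, `partner_cut` 16), `abundance_threshold` (0.01), `seed`
#' (1). A single config seed fans out to per-stage seeds by a stable hash
#' of the stage name, so adding a stage never perturbs earlier stages.
#'
#' @param config list or path to a YAML config file.
#' @param out_dir run directory (created; default `config$out_dir` or a
#'   tempdir subdirectory).
#' @return (invisibly) list with the stage results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- pipeline_defaults(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- file.path(tempdir(), "fermcore_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  cat("", file = log_path)
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                stage, msg), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_line(name, sprintf("done in %.2fs",
                           as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  # --- load or simulate ---
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- stage_seed(cfg$seed, "simulate")
    sim <- stage("simulate", do.call(simulate_dataset, sim_args))
    abundance <- sim$abundance
    flavor <- sim$flavor
    truth <- sim$truth
    truth_json <- list(planted_core = truth$planted_core,
                       active_components = truth$active_components,
                       core_margin = truth$core_margin,
                       params = truth$params, seed = truth$seed)
    jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_abundance_table(abundance, file.path(out_dir, "abundance.tsv"))
    write_flavor_table(flavor, file.path(out_dir, "flavor.tsv"))
  } else {
    inp <- cfg$inputs
    for (f in c(inp$abundance, inp$flavor, inp$annotation))
      if (!file.exists(f)) stop("input file not found: ", f)
    abundance <- stage("read_abundance", read_abundance_table(inp$abundance))
    ann <- if (!is.null(inp$annotation)) read_flavor_annotation(inp$annotation)
           else douchi_flavor_annotation()
    flavor <- stage("read_flavor", read_flavor_table(inp$flavor, ann))
  }
  rel <- if (abundance$proportions) abundance else to_relative_abundance(abundance)

  # --- alpha diversity (counts only make sense for count tables) ---
  div <- NULL
  is_counts <- !abundance$proportions &&
    all(abs(abundance$values - round(abundance$values)) < 1e-8)
  if (is_counts) {
    div <- stage("diversity", alpha_diversity(abundance))
    utils::write.table(div, file.path(out_dir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  summ <- stage("abundance_summary",
                abundance_summary(rel, cfg$abundance_threshold))
  utils::write.table(summ, file.path(out_dir, "abundance_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- ordination, clustering, PERMANOVA ---
  d <- stage("distance", switch(cfg$metric,
                                bray_curtis = bray_curtis(rel),
                                hellinger = hellinger_distance(rel),
                                stop("unknown metric: ", cfg$metric)))
  ord <- stage("pcoa", pcoa(d, n_axes = min(2, nrow(rel$values) - 2)))
  write_matrix_tsv(ord$coordinates, file.path(out_dir, "pcoa_coordinates.tsv"),
                   label = "sample_id")
  utils::write.table(
    data.frame(axis = seq_along(ord$eigenvalues),
               eigenvalue = ord$eigenvalues),
    file.path(out_dir, "pcoa_eigenvalues.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tree <- stage("hca", hca(d))
  writeLines(tree$newick, file.path(out_dir, "dendrogram.nwk"))
  hca_groups <- cut_groups(tree, k = 2)

  perms <- list()
  if (!is.null(rel$group) && length(unique(rel$group)) >= 2) {
    perms$declared <- stage("permanova_declared",
                            permanova(d, rel$group, n_perm = cfg$n_perm,
                                      seed = stage_seed(cfg$seed, "permanova")))
  }
  if (length(unique(hca_groups)) >= 2) {
    perms$hca_k2 <- stage("permanova_hca",
                          permanova(d, hca_groups, n_perm = cfg$n_perm,
                                    seed = stage_seed(cfg$seed, "permanova")))
  }

  # --- flavor block ---
  n <- nrow(flavor$values)
  fp_ncomp <- min(2, n - 2)
  fpca <- stage("flavor_pca", pca_fit(flavor, n_comp = fp_ncomp))
  write_matrix_tsv(fpca$scores, file.path(out_dir, "flavor_pca_scores.tsv"),
                   label = "sample_id")
  write_matrix_tsv(fpca$loadings,
                   file.path(out_dir, "flavor_pca_loadings.tsv"),
                   label = "component_id")
  q2 <- stage("flavor_q2",
              pca_q2(flavor, n_comp = fp_ncomp,
                     seed = stage_seed(cfg$seed, "flavor_q2")))
  utils::write.table(q2, file.path(out_dir, "flavor_pca_q2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  taste <- stage("taste_classes", taste_class_sums(flavor))
  utils::write.table(taste, file.path(out_dir, "taste_class_sums.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- O2PLS ---
  oc <- cfg$o2pls
  if (!is.null(oc$K_range)) {
    cv <- stage("o2pls_cv",
                o2pls_cv(rel, flavor, K_range = oc$K_range,
                         nx_range = oc$nx_range %||% 0:1,
                         ny_range = oc$ny_range %||% 0:1,
                         seed = stage_seed(cfg$seed, "o2pls_cv")))
    model <- cv$model
    utils::write.table(cv$table, file.path(out_dir, "o2pls_cv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    model <- stage("o2pls", o2pls(rel, flavor, K = oc$K %||% 1,
                                  nx = oc$nx %||% 0, ny = oc$ny %||% 0))
  }
  vip <- stage("vip", vip_pred(model))
  vip_df <- data.frame(genus = names(vip), vip = unname(vip))
  vip_df <- vip_df[order(-vip_df$vip), ]
  utils::write.table(vip_df, file.path(out_dir, "vip_pred.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(model$W, file.path(out_dir, "o2pls_W.tsv"),
                   label = "taxon")
  write_matrix_tsv(model$C, file.path(out_dir, "o2pls_C.tsv"),
                   label = "component")
  model_json <- list(K = unname(model$dims["K"]), nx = unname(model$dims["nx"]),
                     ny = unname(model$dims["ny"]), R2X = model$R2X,
                     R2Y = model$R2Y, R2Y_pred = model$R2Y_pred,
                     R2_inner = model$R2_inner, Q2 = model$Q2)
  jsonlite::write_json(model_json, file.path(out_dir, "o2pls_model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- networks and screen ---
  rmat <- stage("correlate",
                correlate(rel, flavor, method = cfg$correlation$method))
  nets <- list()
  for (th in cfg$correlation$thresholds) {
    net <- stage(sprintf("network_%g", th), threshold_network(rmat, th))
    export_network(net, file.path(out_dir, sprintf("network_%g.tsv", th)),
                   ann = flavor$annotation)
    nets[[sprintf("%g", th)]] <- net
  }
  screen_th <- cfg$screen$threshold %||% 0.7
  net_screen <- nets[[sprintf("%g", screen_th)]] %||%
    threshold_network(rmat, screen_th)
  psum <- stage("partner_summary",
                partner_summary(net_screen, flavor$annotation))
  screen <- stage("screen",
                  screen_core(psum, vip, vip_cut = cfg$screen$vip_cut,
                              partner_cut = cfg$screen$partner_cut))
  utils::write.table(as.data.frame(screen),
                     file.path(out_dir, "core_screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_samples = nrow(rel$values),
    n_taxa = ncol(rel$values),
    n_flavor_components = ncol(flavor$values),
    permanova = lapply(perms, function(p)
      list(F = p$F, R2 = p$R2, p = p$p, method = p$method)),
    flavor_pca = list(R2X = fpca$R2X, cum_R2X = fpca$cum_R2X,
                      Q2 = q2$Q2, significant = q2$significant),
    o2pls = model_json,
    n_vip_above_1 = sum(vip >= 1),
    network_edges = lapply(nets, nrow),
    n_aa_correlated = length(attr(psum, "aa_genera")),
    n_vf_correlated = length(attr(psum, "vf_genera")),
    n_both_correlated = length(attr(psum, "both_genera")),
    core_set = attr(screen, "core_set"))
  if (!is.null(truth)) {
    report$planted_core <- truth$planted_core
    report$core_recovered_exactly <-
      setequal(attr(screen, "core_set"), truth$planted_core)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "fermcore",
                   version = as.character(utils::packageVersion("fermcore")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = cfg$seed,
                   config_hash = config_hash(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline", "complete")
  invisible(list(out_dir = out_dir, abundance = abundance, flavor = flavor,
                 truth = truth, diversity = div, pcoa = ord, hca = tree,
                 permanova = perms, flavor_pca = fpca, flavor_q2 = q2,
                 o2pls = model, vip = vip, networks = nets,
                 partner_summary = psum, screen = screen, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_defaults <- function(config) {
  if (is.null(config$inputs) == is.null(config$simulate))
    stop("config must have exactly one of 'inputs' or 'simulate'")
  cfg <- config
  cfg$metric <- cfg$metric %||% "bray_curtis"
  cfg$n_perm <- cfg$n_perm %||% 999
  cfg$seed <- cfg$seed %||% 1
  cfg$abundance_threshold <- cfg$abundance_threshold %||% 0.01
  cfg$o2pls <- cfg$o2pls %||% list(K = 2, nx = 1, ny = 1)
  cfg$correlation <- cfg$correlation %||% list()
  cfg$correlation$method <- cfg$correlation$method %||% "pearson"
  cfg$correlation$thresholds <- cfg$correlation$thresholds %||% c(0.7, 0.8)
  cfg$screen <- cfg$screen %||% list()
  cfg$screen$vip_cut <- cfg$screen$vip_cut %||% 1.0
  cfg$screen$partner_cut <- cfg$screen$partner_cut %||% 16
  if (cfg$screen$vip_cut < 0) stop("vip_cut must be non-negative")
  if (cfg$screen$partner_cut < 1) stop("partner_cut must be >= 1")
  if (!all(cfg$correlation$thresholds > 0 & cfg$correlation$thresholds < 1))
    stop("correlation thresholds must be in (0, 1)")
  cfg
}

# stable per-stage seed: polynomial hash of the stage name folded into the
# base seed, so adding stages never perturbs earlier stages' randomness
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((seed + h) %% .Machine$integer.max)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% (2^31 - 1)
  sprintf("%08x", as.integer(h))
}
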