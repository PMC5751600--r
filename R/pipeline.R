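# Stage orchestration. Each stage reads its predecessor's TSV artifacts
# from disk and writes its own, so every stage is independently testable;
# `run_all()` chains them and writes a manifest with the config, seed and
# input hashes. Outputs are pure functions of (inputs, config, seed).

stage_log <- function(stage, t0) {
  message(sprintf("[modrepo] %-10s %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Simulate a synthetic input bundle to disk
#'
#' @param out_dir output directory.
#' @param config a [run_config()] (its seed drives the generator).
#' @param scfg a [synth_config()].
#' @return `out_dir`, invisibly.
#' @export
stage_simulate <- function(out_dir, config = run_config(),
                           scfg = synth_config()) {
  t0 <- as.numeric(Sys.time())
  bundle <- generate_bundle(scfg, seed = config$seed)
  write_bundle(bundle, out_dir, config)
  stage_log("simulate", t0)
  invisible(out_dir)
}

#' Differential-expression stage
#'
#' Aggregates probes to genes, reports sample dispersion, runs the
#' moderated test and writes `gene_expression.tsv` (aggregated matrix) and
#' `de.tsv`.
#'
#' @param in_dir directory with `probes.tsv`, `metadata.tsv`,
#'   `probe_map.tsv`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return the `de_result`, invisibly.
#' @export
stage_diffexpr <- function(in_dir, out_dir = in_dir,
                           config = run_config()) {
  t0 <- as.numeric(Sys.time())
  probes <- read_expression(file.path(in_dir, "probes.tsv"),
                            file.path(in_dir, "metadata.tsv"))
  pm <- read_probe_map(file.path(in_dir, "probe_map.tsv"))
  em <- aggregate_probes(probes, pm)
  disp <- check_sample_dispersion(em, mult = config$dispersion_mult)
  message(sprintf("[modrepo] sample-mean SD %.4f; %d sample(s) flagged",
                  disp$sd, length(disp$flagged)))
  de <- moderated_test(em, alpha = config$alpha, use_fdr = config$use_fdr)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(em, file.path(out_dir, "gene_expression.tsv"),
                   file.path(out_dir, "metadata.tsv"), config)
  write_de_result(de, file.path(out_dir, "de.tsv"), config)
  stage_log("diffexpr", t0)
  invisible(de)
}

#' Co-expression module stage
#'
#' Restricts the matrix to DE candidates, trims outlier samples, picks the
#' soft power, computes the TOM dissimilarity, detects modules and writes
#' `modules.tsv`, `eigengenes.tsv`, `module_trait.tsv` and `soft_power.tsv`.
#'
#' @param in_dir directory with `gene_expression.tsv`, `metadata.tsv`,
#'   `de.tsv`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return the `coexpr_partition`, invisibly.
#' @export
stage_modules <- function(in_dir, out_dir = in_dir,
                          config = run_config()) {
  t0 <- as.numeric(Sys.time())
  em <- read_expression(file.path(in_dir, "gene_expression.tsv"),
                        file.path(in_dir, "metadata.tsv"))
  de <- read_de_result(file.path(in_dir, "de.tsv"))
  cand <- de$gene[de$candidate]
  if (length(cand) < 3) stop("fewer than 3 candidate genes")
  em <- em[cand, ]
  em <- trim_outlier_samples(em, cut_height = config$sample_cut_height)
  pk <- pick_soft_threshold(em, powers = config$powers,
                            rsq_target = config$rsq_target)
  diss <- compute_tom(em, pk$beta)
  part <- detect_modules(diss, min_size = config$min_module_size,
                         cut_height = config$cut_height)
  mt <- module_trait_correlation(em, part)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_partition(part, file.path(out_dir, "modules.tsv"), config)
  write_tsv(pk$fit, file.path(out_dir, "soft_power.tsv"), config)
  eg <- mt$eigengenes
  eg_long <- data.frame(module = rep(rownames(eg), ncol(eg)),
                        sample = rep(colnames(eg), each = nrow(eg)),
                        value = as.vector(eg), stringsAsFactors = FALSE)
  write_tsv(eg_long, file.path(out_dir, "eigengenes.tsv"), config)
  write_tsv(mt$sample_cor, file.path(out_dir, "module_trait.tsv"), config)
  write_tsv(mt$tissue_tests, file.path(out_dir, "module_tissue_tests.tsv"),
            config)
  stage_log("modules", t0)
  invisible(part)
}

#' Seed-expansion stage
#'
#' One-layer expansion of the seed gene list through the regulatory edge
#' list; writes `expanded_nodes.txt` and `expanded_edges.tsv`.
#'
#' @param in_dir directory with `seeds.txt`, `regulatory.tsv`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return the expanded [regulatory_network()], invisibly.
#' @export
stage_expand <- function(in_dir, out_dir = in_dir,
                         config = run_config()) {
  t0 <- as.numeric(Sys.time())
  seeds <- read_gene_list(file.path(in_dir, "seeds.txt"))
  regnet <- read_regulatory(file.path(in_dir, "regulatory.tsv"))
  exp_net <- expand_seed_network(seeds, regnet)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_list(exp_net$nodes, file.path(out_dir, "expanded_nodes.txt"),
                  config)
  write_regulatory(exp_net, file.path(out_dir, "expanded_edges.tsv"),
                   config)
  stage_log("expand", t0)
  invisible(exp_net)
}

#' Enrichment stage
#'
#' Scores every module's overlap with the expanded-network genes and writes
#' `enrichment.tsv`. Alternatively, with `counts_path` given, scores a
#' published count table directly (no expression inputs needed).
#'
#' @param in_dir directory with `modules.tsv` and `expanded_nodes.txt`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param counts_path optional TSV `module, N, K, n, k`.
#' @return the `enrichment_result`, invisibly.
#' @export
stage_enrich <- function(in_dir, out_dir = in_dir, config = run_config(),
                         counts_path = NULL) {
  t0 <- as.numeric(Sys.time())
  enr <- if (!is.null(counts_path)) {
    score_enrichment_counts(read_tsv(counts_path),
                            log_base = config$log_base)
  } else {
    part <- read_partition(file.path(in_dir, "modules.tsv"))
    net_genes <- read_gene_list(file.path(in_dir, "expanded_nodes.txt"))
    rank_modules(part, net_genes, log_base = config$log_base)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_enrichment(enr, file.path(out_dir, "enrichment.tsv"), config)
  stage_log("enrich", t0)
  invisible(enr)
}

#' Drug-scoring stage
#'
#' Builds the PPI network of every selected module, scores and ranks all
#' drugs by DESS, and writes `drug_scores.tsv`, per-module network exports
#' (`module_<label>_nodes.tsv` / `_edges.tsv`) and the extended
#' drug-target network for the top drugs.
#'
#' @param in_dir directory with `modules.tsv`, `enrichment.tsv`, `de.tsv`,
#'   `seeds.txt`, `expanded_nodes.txt`, `ppi.tsv`, `drug_evidence.tsv`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return the `drug_score_table`, invisibly.
#' @export
stage_score <- function(in_dir, out_dir = in_dir, config = run_config()) {
  t0 <- as.numeric(Sys.time())
  part <- read_partition(file.path(in_dir, "modules.tsv"))
  enr <- read_enrichment(file.path(in_dir, "enrichment.tsv"))
  de <- read_de_result(file.path(in_dir, "de.tsv"))
  seeds <- read_gene_list(file.path(in_dir, "seeds.txt"))
  expanded <- read_gene_list(file.path(in_dir, "expanded_nodes.txt"))
  ppi <- read_ppi(file.path(in_dir, "ppi.tsv"))
  ev <- read_drug_evidence(file.path(in_dir, "drug_evidence.tsv"))
  sel <- enr$module[enr$selected]
  if (!length(sel)) stop("no selected (positively enriched) module")
  modnets <- list()
  for (m in sel) {
    mg <- names(part$labels)[part$labels == m]
    modnets[[m]] <- build_module_network(
      mg, ppi, config$ppi_threshold, de, seeds, expanded,
      k_const = config$k_const, label = m)
  }
  scores <- score_drugs(ev, modnets, enr, ppi, k_const = config$k_const,
                        top_fraction = config$top_fraction)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(scores), file.path(out_dir, "drug_scores.tsv"),
            config)
  for (m in sel)
    write_network_export(modnets[[m]]$nodes, modnets[[m]]$edges,
                         file.path(out_dir, paste0("module_", m)), config)
  top_ids <- scores$drug_id[scores$top]
  ext <- build_extended_drug_network(top_ids, modnets, ev, ppi,
                                     conf_threshold = config$ppi_threshold)
  write_network_export(ext$nodes, ext$edges,
                       file.path(out_dir, "extended_drug_network"), config)
  stage_log("score", t0)
  invisible(scores)
}

#' Run the full pipeline in one directory
#'
#' Chains simulate (optional) -> diffexpr -> modules -> expand -> enrich ->
#' score, then writes `manifest.json` recording the configuration, seed,
#' package version and MD5 hash of every artifact in the directory.
#'
#' @param dir working directory holding inputs and outputs.
#' @param config a [run_config()].
#' @param scfg a [synth_config()]; only used when `simulate = TRUE`.
#' @param simulate generate the inputs first.
#' @return the final `drug_score_table`, invisibly.
#' @export
run_all <- function(dir, config = run_config(), scfg = synth_config(),
                    simulate = TRUE) {
  if (simulate) stage_simulate(dir, config, scfg)
  stage_diffexpr(dir, dir, config)
  stage_modules(dir, dir, config)
  stage_expand(dir, dir, config)
  stage_enrich(dir, dir, config)
  scores <- stage_score(dir, dir, config)
  write_manifest(dir, config)
  invisible(scores)
}

#' Write a run manifest
#'
#' Records the configuration (seed included), the package version and the
#' MD5 hash of every TSV/TXT artifact in `dir`, as JSON. No timestamps, so
#' reruns with the same inputs are byte-identical.
#'
#' @param dir run directory.
#' @param config a [run_config()].
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, config) {
  files <- sort(list.files(dir, pattern = "\\.(tsv|txt)$"))
  hashes <- as.list(tools::md5sum(file.path(dir, files)))
  names(hashes) <- files
  manifest <- list(
    tool = "modrepo",
    version = as.character(utils::packageVersion("modrepo")),
    config = unclass(config),
    files = hashes)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# minimal flag parser: --flag value pairs after the subcommand
parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("missing value for --", key)
    flags[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

cli_config <- function(flags) {
  cfg <- list()
  num <- function(x) as.numeric(x)
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
  if (!is.null(flags$alpha)) cfg$alpha <- num(flags$alpha)
  if (!is.null(flags$power)) cfg$powers <- as.integer(flags$power)
  if (!is.null(flags$cut_height)) cfg$cut_height <- num(flags$cut_height)
  if (!is.null(flags$min_module_size))
    cfg$min_module_size <- as.integer(flags$min_module_size)
  if (!is.null(flags$ppi_threshold))
    cfg$ppi_threshold <- num(flags$ppi_threshold)
  if (!is.null(flags$k_const)) cfg$k_const <- num(flags$k_const)
  if (!is.null(flags$log_base)) cfg$log_base <- num(flags$log_base)
  if (!is.null(flags$top_fraction))
    cfg$top_fraction <- num(flags$top_fraction)
  do.call(run_config, cfg)
}

#' Command-line entry point
#'
#' `Rscript -e 'modrepo::modrepo_cli()' <subcommand> --out-dir DIR [flags]`
#' with subcommand one of `simulate`, `diffexpr`, `modules`, `expand`,
#' `enrich`, `score`, `all`. Flags: `--seed`, `--alpha`, `--power`,
#' `--cut-height`, `--min-module-size`, `--ppi-threshold`, `--k-const`,
#' `--log-base`, `--top-fraction`, `--in-dir`, `--out-dir`, and for
#' `enrich` optionally `--counts` (a published count table). Progress and
#' stage timings go to stderr.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the final stage's value.
#' @export
modrepo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: modrepo <simulate|diffexpr|modules|expand|enrich|score|all>",
         " --out-dir DIR [flags]")
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  out_dir <- flags$out_dir
  if (is.null(out_dir)) stop("--out-dir is required")
  in_dir <- if (is.null(flags$in_dir)) out_dir else flags$in_dir
  cfg <- cli_config(flags)
  res <- switch(cmd,
    simulate = stage_simulate(out_dir, cfg),
    diffexpr = stage_diffexpr(in_dir, out_dir, cfg),
    modules = stage_modules(in_dir, out_dir, cfg),
    expand = stage_expand(in_dir, out_dir, cfg),
    enrich = stage_enrich(in_dir, out_dir, cfg,
                          counts_path = flags$counts),
    score = stage_score(in_dir, out_dir, cfg),
    all = run_all(out_dir, cfg),
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
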