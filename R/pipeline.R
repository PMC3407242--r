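#' Run the full breed-divergence analysis pipeline
#'
#' Orchestrates every stage over one dataset: simulate or load genotypes,
#' QC, allele sharing with clustering, PCoA embeddings (full panel plus
#' configured subsets), pairwise F_ST with bootstrap SDs, outlier ranking
#' with chromosomal enrichment, haplotype-window EM, diversity indices and
#' the calibration verdict. Every table is written as TSV under
#' `output_dir`, and a manifest (seed, input hashes, stage outputs,
#' timings) is written as YAML. Identical config and seed give identical
#' outputs.
#'
#' @param config A config list, or path to a YAML file. Top-level keys:
#'   `seed`, `output_dir`, exactly one of `simulation` / `input`, and
#'   optional `qc`, `pca`, `fst`, `haplotypes`, `diversity`,
#'   `calibration`. See the packaged demo config
#'   (`system.file("extdata", "demo_config.yaml", package = "breedline")`).
#' @param output_dir Overrides `config$output_dir`.
#' @return The manifest, invisibly: list with `seed`, `stages` (name,
#'   outputs, seconds) and `outputs` (all files written).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "output_dir", "simulation", "input", "qc", "pca",
             "fst", "haplotypes", "diversity", "calibration")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key: ", paste(unknown, collapse = ", ")))
  }
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort("config must contain exactly one of 'simulation' or 'input'")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  if (is.null(out_dir)) abort("output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(seed = seed, stages = list(), outputs = character(0))
  t_write <- function(x, name) {
    path <- file.path(out_dir, name)
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  # ---- stage 1: data --------------------------------------------------------
  poll_window_ids <- NULL
  dat <- stage("data", function() {
    if (has_sim) {
      s <- config$simulation
      sim <- simulate_balding_nichols(
        n_pops = s$n_pops %||% 2,
        drift = unlist(s$drift) %||% 0.062,
        n_snps = s$n_snps %||% 5000,
        samples_per_pop = unlist(s$samples_per_pop) %||% 50,
        missing_rate = s$missing_rate %||% 0,
        seed = seed + 100L)
      if (isTRUE(s$poll_block)) {
        chr10 <- sim$genotypes$map$snp_id[sim$genotypes$map$chromosome == "10"]
        if (length(chr10) < 4) abort("need >= 4 SNPs on chromosome 10 for the poll block")
        window <- chr10[1:4]
        pops <- unique(sim$labels$population)
        rows <- rep_len(c("Florida Native", "Louisiana Native",
                          "Poll Merino", "Merino"), length(pops))
        blk <- poll_block(window, setNames(rows, pops))
        inj <- inject_haplotype_block(sim$genotypes, sim$labels, sim$truth,
                                      blk, seed = seed + 150L)
        sim$genotypes <- inj$genotypes
        sim$truth <- inj$truth
        poll_window_ids <<- window
      }
      t_write(sim$truth$ancestral, "truth_ancestral.tsv")
      t_write(sim$truth$pop_freq, "truth_pop_freq.tsv")
      t_write(sim$labels, "labels.tsv")
      paths <- write_ped_map(sim$genotypes, file.path(out_dir, "genotypes"))
      manifest$outputs <<- c(manifest$outputs, unname(paths))
      list(genotypes = sim$genotypes, labels = sim$labels)
    } else {
      pm <- read_ped_map(config$input$ped, config$input$map)
      manifest$input_hashes <<- as.list(tools::md5sum(
        c(config$input$ped, config$input$map, config$input$labels)))
      list(genotypes = pm$genotypes,
           labels = read_pop_labels(config$input$labels))
    }
  })
  g <- dat$genotypes
  labels <- dat$labels

  # ---- stage 2: QC ----------------------------------------------------------
  qc <- stage("qc", function() {
    q <- config$qc
    res <- apply_qc(g,
                    snp_call_rate_min = q$snp_call_rate_min %||% 0,
                    sample_call_rate_min = q$sample_call_rate_min %||% 0,
                    maf_min = q$maf_min %||% 0)
    t_write(res$report, "qc_report.tsv")
    res
  })
  g <- qc$genotypes
  labels <- labels[labels$sample_id %in% rownames(g$codes), ]

  # ---- stage 3: allele sharing ----------------------------------------------
  sh <- stage("sharing", function() {
    s <- sharing_matrix(g)
    path <- file.path(out_dir, "sharing_matrix.tsv")
    write_sharing_tsv(s, path)
    manifest$outputs <<- c(manifest$outputs, path)
    ord <- cluster_order(s)
    t_write(tibble(position = seq_along(ord$order),
                   sample_id = ord$labels[ord$order]),
            "cluster_order.tsv")
    s
  })

  # ---- stage 4: F_ST --------------------------------------------------------
  fst_cfg <- config$fst
  fst_res <- stage("fst", function() {
    n_boot <- fst_cfg$n_boot %||% 200
    pairs_tbl <- pairwise_fst_matrix(g, labels, n_boot = n_boot,
                                     seed = seed + 300L)
    t_write(pairs_tbl, "fst_pairs.tsv")
    pops <- sort(unique(labels$population))[1:2]
    comp <- fst_components(g, labels, pops)
    per_snp <- dplyr::left_join(
      as_tibble(comp)[, c("snp_id", "fst")],
      g$map[, c("snp_id", "chromosome", "position_bp")], by = "snp_id")
    t_write(per_snp, "fst_per_snp.tsv")
    list(pairs = pairs_tbl, comp = comp)
  })

  # ---- stage 5: ranking and enrichment --------------------------------------
  ranked <- stage("rank_enrich", function() {
    fractions <- unlist(fst_cfg$top_fractions) %||% c(0.01, 0.05)
    tops <- lapply(fractions, function(q) {
      top <- rank_top_fraction(fst_res$comp, q)
      t_write(tibble(rank = seq_along(top), snp_id = top),
              sprintf("top_snps_%g.tsv", 100 * q))
      enr <- chromosome_enrichment(top, g$map)
      t_write(enr, sprintf("enrichment_%g.tsv", 100 * q))
      top
    })
    names(tops) <- as.character(fractions)
    tops
  })

  # ---- stage 6: PCoA embeddings ---------------------------------------------
  stage("pca", function() {
    k <- config$pca$k %||% 2
    full <- pcoa_from_sharing(sh, k = k)
    t_write(tidy.pcoa_result(full), "pca_full.tsv")
    rf <- config$pca$random_fraction %||% 0.01
    rnd <- subset_and_embed(g, rf, k = k, seed = seed + 200L)
    t_write(tidy.pcoa_result(rnd), "pca_random_subset.tsv")
    top1 <- ranked[[1]]
    topemb <- subset_and_embed(g, top1, k = k)
    t_write(tidy.pcoa_result(topemb), "pca_top_fst.tsv")
    scores <- tibble(
      embedding = c("full", "random_subset", "top_fst"),
      separation = c(separation_score(full, labels),
                     separation_score(rnd, labels),
                     separation_score(topemb, labels)))
    t_write(scores, "separation_scores.tsv")
    scores
  })

  # ---- stage 7: haplotype window --------------------------------------------
  window <- config$haplotypes$window %||% poll_window_ids
  if (!is.null(window)) {
    stage("haplotypes", function() {
      named <- unlist(config$haplotypes$named) %||% poll_window()$named
      sett <- em_settings(seed = seed + 400L)
      tabs <- lapply(unique(labels$population), function(pop) {
        em_haplotype_frequencies(g, window, pop_samples(labels, pop), sett)
      })
      names(tabs) <- unique(labels$population)
      t_write(haplotype_report(tabs, named, sett$min_report_freq),
              "haplotype_table.tsv")
    })
  }

  # ---- stage 8: diversity ---------------------------------------------------
  stage("diversity", function() {
    t_write(diversity_report(g, labels,
                             g_copies = config$diversity$g_copies),
            "diversity.tsv")
  })

  # ---- stage 9: calibration -------------------------------------------------
  stage("calibration", function() {
    fix <- read_fst_fixture(config$calibration$fixture)
    calib <- calibration_table(fix$fst,
                               read_categories(config$calibration$categories))
    t_write(calib, "calibration_table.tsv")
    candidate <- 100 * fst_res$pairs$fst[1]
    t_write(breed_verdict(candidate, calib), "verdict.tsv")
  })

  manifest$package_version <- as.character(utils::packageVersion("breedline"))
  manifest$outputs <- unname(manifest$outputs)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
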