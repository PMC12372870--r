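#' Analysis configuration
#'
#' Collects and validates every tunable of the pipeline. Thresholds default
#' to the study settings: binders are preys with log2FC > 0.5 and p < 0.05
#' over the empty-vector control; the correlated-binder subset requires
#' Pearson r > 0.3 to the bait; pi-ranked ORA selections take the top 100.
#'
#' @param seed Integer seed controlling simulation and decoy draws.
#' @param out_dir Output directory for [run_apms()].
#' @param sim [sim_params()] object used when no input paths are given.
#' @param abundance_path,design_path,gmt_path Optional paths to an existing
#'   abundance TSV, design TSV and GMT collection; when `abundance_path` is
#'   `NULL` the pipeline simulates its own data (and builds a
#'   module-plus-decoys collection unless `gmt_path` is given).
#' @param fc_threshold,p_threshold Binder-calling thresholds (strict
#'   inequalities), both > 0.
#' @param r_cutoff Correlation cutoff in (0, 1).
#' @param min_per_group Minimum non-missing values per (condition,
#'   treatment) group, >= 2.
#' @param min_points Minimum paired points for the bait regression, >= 3.
#' @param test_variant `"student"` or `"welch"`.
#' @param top_n Size of the pi-ranked ORA selection.
#' @param n_decoy_sets Decoy sets in the generated collection.
#' @param batch_scope Centering scope, see [center_batches()].
#' @param pseudocount Pseudocount for [log2_transform()].
#' @param bait_id Protein id of the bait row.
#' @return List of class `apms_config`.
#' @export
apms_config <- function(seed = 1,
                        out_dir = NULL,
                        sim = sim_params(seed = seed),
                        abundance_path = NULL,
                        design_path = NULL,
                        gmt_path = NULL,
                        fc_threshold = 0.5,
                        p_threshold = 0.05,
                        r_cutoff = 0.3,
                        min_per_group = 2,
                        min_points = 3,
                        test_variant = c("student", "welch"),
                        top_n = 100,
                        n_decoy_sets = 19,
                        batch_scope = c("batch", "batch_treatment"),
                        pseudocount = 0,
                        bait_id = "hSFPQ") {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
              abundance_path = abundance_path, design_path = design_path,
              gmt_path = gmt_path, fc_threshold = fc_threshold,
              p_threshold = p_threshold, r_cutoff = r_cutoff,
              min_per_group = as.integer(min_per_group),
              min_points = as.integer(min_points),
              test_variant = match.arg(test_variant),
              top_n = as.integer(top_n),
              n_decoy_sets = as.integer(n_decoy_sets),
              batch_scope = match.arg(batch_scope),
              pseudocount = pseudocount, bait_id = bait_id)
  class(cfg) <- "apms_config"
  validate_config(cfg)
}

#' @rdname apms_config
#' @param config An `apms_config` object.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "apms_config")) {
    stop("config error: not an apms_config object", call. = FALSE)
  }
  if (config$fc_threshold <= 0 || config$p_threshold <= 0 ||
      config$p_threshold > 1) {
    stop("config error: fc_threshold must be > 0 and p_threshold in (0, 1]",
         call. = FALSE)
  }
  if (config$r_cutoff <= 0 || config$r_cutoff >= 1) {
    stop("config error: r_cutoff must lie in (0, 1)", call. = FALSE)
  }
  if (config$min_per_group < 2 || config$min_points < 3 ||
      config$top_n < 1) {
    stop("config error: min_per_group >= 2, min_points >= 3, top_n >= 1",
         call. = FALSE)
  }
  if (is.null(config$abundance_path)) validate_sim_params(config$sim)
  invisible(config)
}

config_to_yaml <- function(config, path) {
  ser <- config
  ser$out_dir <- NULL  # not part of the analysis; keeps runs relocatable
  ser$sim <- unclass(ser$sim)
  ser$sim$effects <- as.list(ser$sim$effects)
  class(ser) <- NULL
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Run the full differential-interactome pipeline
#'
#' Executes simulate (or load) -> log2 + batch centering + observation
#' filter -> EV enrichment and Venn partition -> bait regression and
#' correlated-binder selection -> matched-ratio contrasts with pi ranking
#' -> gene-set ORA, independently for each treatment, and (when ground
#' truth is available) an evaluation report against the planted truth.
#'
#' All intermediate tables are written as plain TSV under `out_dir`, each
#' with a header comment recording the package version, a hash of the
#' resolved configuration, and the seed; identical config and seed give
#' byte-identical output. Any stage error aborts the run, removes the
#' files already written, and names the failing stage.
#'
#' @param config An [apms_config()] object; `out_dir` must be set.
#' @return Invisibly, a list with elements `rel` (centered matrix),
#'   `enrichment`, `venn`, `regression` (per-treatment
#'   [bait_correct()] results), `selected` (per-treatment correlated-binder
#'   sets), `contrasts` (per treatment x contrast ranked tables), `ora`
#'   (per treatment x contrast), `gene_sets`, `sim` (when simulated),
#'   `evaluation` (when truth is available), and `files` (paths written).
#' @export
run_apms <- function(config) {
  validate_config(config)
  if (is.null(config$out_dir)) {
    stop("config error: out_dir must be set", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stage <- "setup"
  result <- tryCatch(
    run_apms_impl(config, function(p) written <<- c(written, p),
                  function(s) stage <<- s),
    error = function(e) {
      unlink(written)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  result$files <- written
  invisible(result)
}

run_apms_impl <- function(config, note_file, note_stage) {
  out <- config$out_dir
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  note_stage("config")
  cfg_path <- file.path(out, "config.yaml")
  config_to_yaml(config, cfg_path)
  note_file(cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  hdr <- c(paste("apmspi", as.character(utils::packageVersion("apmspi"))),
           paste("config_hash", cfg_hash),
           paste("seed", config$seed))
  say("config hash ", cfg_hash, "; seed ", config$seed)
  say("thresholds: log2FC > ", config$fc_threshold, ", p < ",
      config$p_threshold, ", Pearson r > ", config$r_cutoff,
      ", top_n = ", config$top_n)

  note_stage("input")
  sim <- NULL
  if (is.null(config$abundance_path)) {
    say("simulating: ", config$sim$n_proteins, " proteins, ",
        config$sim$n_binders_per_class, " binders/class, ",
        config$sim$n_replicates, " replicate batches")
    design <- make_design(config$sim$n_replicates)
    sim <- simulate_apms(config$sim, design)
    abundance <- sim$abundance
    f <- file.path(out, "abundance.tsv")
    write_abundance_tsv(abundance, f, hdr); note_file(f)
    f <- file.path(out, "design.tsv")
    write_design_tsv(design, f, hdr); note_file(f)
    note_file(write_truth_tsv(sim$truth, out, hdr))
  } else {
    say("loading abundance from ", config$abundance_path)
    abundance <- read_abundance_tsv(config$abundance_path)
    design <- read_design_tsv(config$design_path)
  }
  validate_design(design)
  if (!config$bait_id %in% rownames(abundance)) {
    stop("bait row '", config$bait_id, "' missing from the abundance matrix")
  }

  gene_sets <- if (!is.null(config$gmt_path)) {
    say("loading gene sets from ", config$gmt_path)
    read_gmt(config$gmt_path)
  } else if (!is.null(sim)) {
    gs <- make_gene_sets(sim$truth, n_decoy = config$n_decoy_sets,
                         seed = config$seed + 1L)
    f <- file.path(out, "gene_sets.gmt")
    write_gmt(gs, f); note_file(f)
    gs
  } else NULL

  note_stage("normalize")
  lm2 <- log2_transform(abundance, config$pseudocount)
  rel <- center_batches(lm2, design, scope = config$batch_scope)
  rel <- filter_min_observed(rel, design, config$min_per_group,
                             always_keep = config$bait_id)
  say("retained ", nrow(rel), "/", nrow(abundance),
      " proteins after the min-observation filter")
  f <- file.path(out, "relative_log2.tsv")
  write_abundance_tsv(rel, f, c(hdr, "provenance centered")); note_file(f)

  treatments <- intersect(apms_treatments, unique(design$treatment))
  enrichment <- list(); venn <- list(); regression <- list()
  selected <- list(); contrasts <- list(); ora <- list()

  for (treat in treatments) {
    note_stage(paste0("enrich:", treat))
    enr <- call_binders(
      ev_enrichment(rel, design, treatments = treat,
                    variant = config$test_variant,
                    bait_id = config$bait_id,
                    min_per_group = config$min_per_group),
      config$fc_threshold, config$p_threshold)
    enrichment[[treat]] <- enr
    sets <- binder_sets(enr)
    vp <- venn_partition(sets[[paste0("WT.", treat)]],
                         sets[[paste0("ALT.", treat)]],
                         sets[[paste0("NLS.", treat)]])
    venn[[treat]] <- vp
    say(treat, ": binders over EV -- WT ",
        length(sets[[paste0("WT.", treat)]]), ", ALT ",
        length(sets[[paste0("ALT.", treat)]]), ", NLS ",
        length(sets[[paste0("NLS.", treat)]]), "; triple overlap ",
        round(100 * attr(vp, "triple_fraction"), 1), "% of the union")
    f <- file.path(out, paste0("enrichment_", treat, ".tsv"))
    write_tsv_commented(enr, f, hdr); note_file(f)
    vdf <- as.data.frame(vp)
    vdf <- rbind(vdf, data.frame(region = "union",
                                 count = attr(vp, "union_size")))
    f <- file.path(out, paste0("venn_", treat, ".tsv"))
    write_tsv_commented(vdf, f, hdr); note_file(f)

    note_stage(paste0("regress:", treat))
    bc <- bait_correct(rel, design, treat, bait_id = config$bait_id,
                       min_points = config$min_points)
    regression[[treat]] <- bc
    universe <- unique(unlist(sets[paste0(apms_bait_conditions, ".",
                                          treat)]))
    sel <- select_correlated_binders(bc$fits, universe, config$r_cutoff)
    selected[[treat]] <- sel
    say(treat, ": ", length(universe), " binders of any variant; ",
        length(sel), " pass Pearson r > ", config$r_cutoff)
    fits <- bc$fits
    fits$selected <- fits$protein_id %in% sel
    f <- file.path(out, paste0("regression_", treat, ".tsv"))
    write_tsv_commented(fits, f, hdr); note_file(f)
    f <- file.path(out, paste0("corrected_", treat, ".tsv"))
    write_abundance_tsv(bc$corrected, f, c(hdr, "provenance bait_corrected"))
    note_file(f)

    note_stage(paste0("contrast:", treat))
    for (ctr in names(apms_contrast_defs)) {
      ranked <- rank_binders(
        contrast_tests(bc$corrected, design, ctr, treat), sel)
      contrasts[[treat]][[ctr]] <- ranked
      f <- file.path(out, paste0("contrast_", treat, "_", ctr, ".tsv"))
      write_tsv_commented(ranked, f, hdr); note_file(f)
    }

    if (!is.null(gene_sets)) {
      note_stage(paste0("ora:", treat))
      for (ctr in names(apms_contrast_defs)) {
        ranked <- contrasts[[treat]][[ctr]]
        if (sum(!is.na(ranked$rank)) == 0) next
        res <- ora_top_pi(ranked, gene_sets, top_n = config$top_n)
        ora[[treat]][[ctr]] <- res
        f <- file.path(out, paste0("ora_", treat, "_", ctr, ".tsv"))
        write_tsv_commented(res, f, hdr); note_file(f)
      }
    }
  }

  result <- list(rel = rel, design = design, enrichment = enrichment,
                 venn = venn, regression = regression, selected = selected,
                 contrasts = contrasts, ora = ora, gene_sets = gene_sets,
                 sim = sim, config = config)

  if (!is.null(sim)) {
    note_stage("evaluate")
    result$evaluation <- evaluate_run(result, sim)
    f <- file.path(out, "evaluation.tsv")
    write_tsv_commented(result$evaluation, f, hdr); note_file(f)
    for (i in seq_len(nrow(result$evaluation))) {
      say("evaluation: ", result$evaluation$metric[i], " [",
          result$evaluation$treatment[i], "] = ",
          signif(result$evaluation$value[i], 4))
    }
  }

  note_stage("log")
  f <- file.path(out, "run_log.txt")
  writeLines(log_lines, f); note_file(f)
  result
}
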