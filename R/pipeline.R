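## Pipeline configuration and the end-to-end demo orchestration.

#' Default pipeline configuration
#'
#' The QC defaults are the screen's printed settings: GRM marker set at
#' MAF >= 5%, call rate >= 95%, LD-pruned to r^2 <= 0.8 in 200 kb windows
#' sliding by 5 kb; single-marker scan set at MAF > 5%, call rate > 80%.
#' Pathway features need >= 2 genes and >= 200 markers; CVAT significance
#' uses permutation empirical p-values (default 1e5 permutations; the
#' full-fidelity setting is 1e6) and the heritability permutation null
#' uses 1000 phenotype permutations.
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "rapasens_out",
    qc = list(
      grm = list(maf_min = 0.05, callrate_min = 0.95, ld_prune = TRUE,
                 r2_max = 0.8, window_bp = 200000L, step_bp = 5000L),
      scan = list(maf_min = 0.05, callrate_min = 0.80)),
    feature_window_bp = 1000L,
    gene_min_markers = 1L,
    pathway_min_genes = 2L,
    pathway_min_markers = 200L,
    n_perm = 1e5,
    h2_permutations = 1000L,
    bootstrap = list(sizes = NULL, n_reps = 200L),
    sim = list(
      n_lines = 140L, n_markers = 65000L, h2 = 0.8, n_causal = 500L,
      n_batches = 4L, n_reference = 4L,
      n_vials = 4L, larvae_per_vial = 40L, sd_days = 1, survival = 0.85,
      n_genes = 400L, gene_span_bp = 20000L, n_pathways = 25L,
      pathway_min_markers = 200L,
      met = list(n_metabolites = 154L, reps = 2L, n_overlap = 84L,
                 n_interaction = 40L, interaction_sd = 0.8,
                 n_shared = 10L, shared_effect = -0.5,
                 attenuation = 0.4, starvation_delta = 2,
                 batch_location = 0.5, batch_scale = 1),
      starvation = list(a = 20.53, b = 2.77, c = 10.01,
                        times = c(0, 2, 4, 6, 8), reps = 5L,
                        n_metabolites = 90L, noise_sd = 0.2,
                        n_single_missing = 4L, n_double_missing = 2L,
                        dup_pairs = 3L))
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the matching [default_config()]
#' entries; everything else keeps its default.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

## recursive list -> flat "a.b: value" lines for the run log
.flatten_config <- function(x, prefix = "") {
  out <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(v)) out <- c(out, .flatten_config(v, key))
    else out <- c(out, sprintf("%s: %s", key, paste(format(v), collapse = ",")))
  }
  out
}

#' Run the full pipeline on a simulated study
#'
#' Generates a synthetic study at the configured scale and runs every
#' stage end to end: pupation phenotyping and normalization, gBLUP/REML
#' SNP heritability with permutation (and optional bootstrap) resampling,
#' single-marker scan, gene/gene+-1kb/pathway CVAT, metabolome
#' normalization, batch correction, PCA and mixed models, and projection
#' onto the starvation axis with the displacement test. All outputs are
#' plain TSV/JSON plus PLINK genotypes, written deterministically: a
#' fixed seed yields byte-identical output directories.
#'
#' @param config configuration list (see [default_config()] /
#'   [read_config()]).
#' @param outdir output directory (created; existing files overwritten).
#' @param stages subset of
#'   `c("simulate", "phenotype", "h2", "scan", "cvat", "metabolome",
#'   "project")`; stages build on earlier ones, which always run.
#' @return (invisibly) a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(),
                         outdir = config$outdir,
                         stages = c("simulate", "phenotype", "h2", "scan",
                                    "cvat", "metabolome", "project")) {
  seed <- config$seed
  sim <- config$sim
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(outdir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  res <- list()

  ## --- simulate the study --------------------------------------------
  G <- simulate_genotypes(sim$n_lines, sim$n_markers, seed = seed)
  covariates <- with_stage_seed(seed, "covariates", data.frame(
    line = G$line_ids,
    wolbachia = stats::rbinom(sim$n_lines, 1, 0.5),
    inv_2Lt = stats::rbinom(sim$n_lines, 1, 0.2),
    inv_2RNS = stats::rbinom(sim$n_lines, 1, 0.2),
    inv_3RP = stats::rbinom(sim$n_lines, 1, 0.2),
    inv_3RK = stats::rbinom(sim$n_lines, 1, 0.2),
    inv_3RMo = stats::rbinom(sim$n_lines, 1, 0.2),
    stringsAsFactors = FALSE))
  ph <- simulate_phenotype(G, sim$h2, n_causal = sim$n_causal,
                           covariates = covariates, seed = seed)
  ## map the Gaussian liability onto a right-skewed delay scale (as the
  ## screen's delays are: bounded just below zero, long right tail); the
  ## Box-Cox step of the normalization then recovers the liability scale
  base_delay <- stats::setNames(exp(0.45 * (ph$phenotype$delay - 2)) - 0.5,
                                ph$phenotype$line)

  ref_lines <- G$line_ids[seq_len(sim$n_reference)]
  other <- setdiff(G$line_ids, ref_lines)
  batches <- sprintf("batch%02d", seq_len(sim$n_batches))
  batch_of <- stats::setNames(batches[(seq_along(other) - 1L) %% sim$n_batches + 1L],
                              other)
  ## bounded offsets keep every measured delay above -1 day, where the
  ## shifted Box-Cox transform is defined
  batch_offsets <- with_stage_seed(seed, "batch-offsets",
                                   stats::setNames(stats::runif(sim$n_batches, -0.4, 0.4),
                                                   batches))

  records <- do.call(rbind, lapply(seq_along(batches), function(bi) {
    b <- batches[bi]
    lines_b <- c(ref_lines, names(batch_of)[batch_of == b])
    lm <- data.frame(line = lines_b, control = 10,
                     rapamycin = 10 + base_delay[lines_b] + batch_offsets[b],
                     stringsAsFactors = FALSE)
    simulate_pupation_records(lm, n_vials = sim$n_vials,
                              larvae_per_vial = sim$larvae_per_vial,
                              sd_days = sim$sd_days, survival = sim$survival,
                              batch_design = stats::setNames(rep(b, length(lines_b)),
                                                             lines_b),
                              seed = stage_seed(seed, paste0("pupation-", b)))
  }))
  write_plink(G, file.path(outdir, "genotypes"))
  write_tsv(covariates, file.path(outdir, "covariates.tsv"))
  write_tsv(records, file.path(outdir, "pupation_records.tsv"))
  res$genotypes <- G

  ## --- phenotype ------------------------------------------------------
  delays <- developmental_delay(summarize_pupation(records))
  delays <- normalize_delay(delays, ref_lines)
  write_tsv(delays, file.path(outdir, "phenotypes.tsv"))
  res$phenotypes <- delays

  ## association set: non-reference lines, one batch each
  assoc <- delays[!delays$is_reference, , drop = FALSE]
  keep_idx <- match(assoc$line, G$line_ids)
  Gsub <- subset_lines(G, keep_idx)
  y <- stats::setNames(assoc$normalized, assoc$line)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(covariates[keep_idx, -1, drop = FALSE]))

  ## --- heritability, scan, CVAT --------------------------------------
  ann <- simulate_annotations(G$map, sim$n_genes, sim$gene_span_bp, seed = seed)
  pathways <- simulate_gene_sets(ann$gene, sim$n_pathways, seed = seed)
  cfg2 <- config
  cfg2$pathway_min_markers <- sim$pathway_min_markers
  sa <- run_set_analysis(Gsub, y, X,
                         annotations = if (any(c("cvat", "scan") %in% stages)) ann else NULL,
                         pathways = if ("cvat" %in% stages) pathways else NULL,
                         config = cfg2)
  res$fit <- sa$fit
  perm <- permute_h2(unname(y), X, sa$K, n_perm = config$h2_permutations,
                     seed = seed)
  res$permutation <- perm
  wj(list(n_lines = length(y), m_markers = sa$fit$n,
          sigma2_g = sa$fit$sigma2_g, sigma2_e = sa$fit$sigma2_e,
          h2_snp = sa$fit$h2, h2_se = sa$fit$h2_se,
          boundary = sa$fit$boundary,
          permutation_p = perm$p_value, permutation_count = perm$count,
          n_permutations = config$h2_permutations), "h2.json")
  write_tsv(data.frame(h2_perm = perm$h2_perm),
            file.path(outdir, "h2_permutations.tsv"))
  if (!is.null(config$bootstrap$sizes)) {
    bs <- bootstrap_h2(unname(y), X, sa$K, sizes = config$bootstrap$sizes,
                       n_reps = config$bootstrap$n_reps, seed = seed)
    write_tsv(bs, file.path(outdir, "h2_bootstrap.tsv"))
    res$bootstrap <- bs
  }
  write_tsv(sa$scan, file.path(outdir, "scan.tsv"))
  for (lv in c("gene", "gene_1kb", "pathway"))
    if (!is.null(sa[[lv]]))
      write_tsv(sa[[lv]], file.path(outdir, paste0("cvat_", lv, ".tsv")))
  res$setassoc <- sa

  if (!any(c("metabolome", "project") %in% stages)) {
    wj(list(h2_true = ph$truth$h2_true, h2_realized = ph$truth$h2_realized,
            n_causal = length(ph$truth$causal),
            batch_offsets = as.list(batch_offsets)), "truth.json")
    .write_pipeline_log(config, outdir)
    return(invisible(res))
  }

  ## --- metabolome and starvation axis --------------------------------
  stv <- sim$starvation
  tc <- simulate_starvation_timecourse(
    a = stv$a, b = stv$b, c = stv$c, times = stv$times, reps = stv$reps,
    n_metabolites = stv$n_metabolites, noise_sd = stv$noise_sd,
    n_single_missing = stv$n_single_missing,
    n_double_missing = stv$n_double_missing,
    dup_pairs = stv$dup_pairs, seed = seed)
  truth_tc <- attr(tc, "truth")

  ms <- sim$met
  ## matched metabolites: query met i <-> reference metabolite i
  n_overlap <- min(ms$n_overlap, stv$n_metabolites, ms$n_metabolites)
  ref_base <- sprintf("ref%03d", seq_len(n_overlap))
  query_names <- sprintf("met%03d", seq_len(n_overlap))
  dup_tab <- truth_tc$dup_pairs
  ref_key <- ifelse(ref_base %in% (dup_tab$base %||% character(0)),
                    paste0(ref_base, "_pos"), ref_base)
  name_map <- data.frame(ref = ref_key, query = query_names,
                         stringsAsFactors = FALSE)
  if (!is.null(dup_tab)) {
    extra <- dup_tab[dup_tab$base %in% ref_base, , drop = FALSE]
    if (nrow(extra))
      name_map <- rbind(name_map,
                        data.frame(ref = extra$ref_b,
                                   query = query_names[match(extra$base, ref_base)],
                                   stringsAsFactors = FALSE))
  }

  effects <- with_stage_seed(seed, "met-effects", {
    e <- matrix(0, ms$n_metabolites, 3,
                dimnames = list(NULL, c("treatment", "phenotype", "interaction")))
    shared <- sample.int(ms$n_metabolites, ms$n_shared)
    e[shared, "treatment"] <- ms$shared_effect
    inter <- sample.int(ms$n_metabolites, ms$n_interaction)
    resp <- numeric(ms$n_metabolites)
    resp[inter] <- stats::rnorm(ms$n_interaction, 0, ms$interaction_sd)
    ## starvation-like displacement of rapamycin-treated sensitive samples
    ## along the reference loadings of the matched metabolites
    resp[seq_len(n_overlap)] <- resp[seq_len(n_overlap)] +
      ms$starvation_delta * truth_tc$loadings[seq_len(n_overlap)] /
        max(abs(truth_tc$loadings[seq_len(n_overlap)]))
    ## resistant lines show the same response, attenuated: a common
    ## treatment component plus the sensitive-only remainder
    e[, "treatment"] <- e[, "treatment"] + ms$attenuation * resp
    e[, "interaction"] <- (1 - ms$attenuation) * resp
    e
  })
  met <- simulate_metabolome(
    n_metabolites = ms$n_metabolites, effects = effects,
    batch_shifts = data.frame(batch = c("mb1", "mb2"),
                              location = c(0, ms$batch_location),
                              scale = c(1, ms$batch_scale)),
    reps = ms$reps, seed = seed)
  norm <- normalize_metabolome(met$matrix)
  corr <- correct_batch(norm)
  pca <- pca_scores(corr)
  ia <- interaction_anova(corr)
  eff_s <- treatment_effects_by_class(corr, "sensitive")
  eff_r <- treatment_effects_by_class(corr, "resistant")
  conc <- effect_sign_concordance(eff_r$beta, eff_s$beta)
  write_metabolome(met$matrix, file.path(outdir, "metabolome_raw.tsv"),
                   file.path(outdir, "metabolome_meta.tsv"))
  write_tsv(ia, file.path(outdir, "metabolome_anova.tsv"))
  write_tsv(eff_s, file.path(outdir, "treatment_effects_sensitive.tsv"))
  write_tsv(eff_r, file.path(outdir, "treatment_effects_resistant.tsv"))
  wj(list(rho = conc$rho, p_value = conc$p_value,
          n_fdr05_sensitive = sum(eff_s$q_value < 0.05, na.rm = TRUE),
          n_fdr05_resistant = sum(eff_r$q_value < 0.05, na.rm = TRUE)),
     "concordance.json")
  res$metabolome <- list(matrix = corr, pca = pca, anova = ia,
                         effects_sensitive = eff_s, effects_resistant = eff_r,
                         concordance = conc)

  hp <- harmonize(tc, corr, name_map, dup_pairs = dup_tab)
  axis <- fit_reference_axis(hp)
  scores <- project(hp, axis)
  disp <- displacement_test(scores, corr$meta)
  write_tsv(data.frame(sample = names(scores), score = scores,
                       corr$meta[match(names(scores), corr$meta$sample),
                                 c("line", "class", "treatment")]),
            file.path(outdir, "projection_scores.tsv"))
  wj(list(metabolites = axis$metabolites, loading = axis$loading,
          means = axis$means, orientation = axis$orientation,
          var_frac = axis$var_frac,
          a = axis$trajectory$a, b = axis$trajectory$b, c = axis$trajectory$c,
          r2 = axis$trajectory$r2), "starvation_axis.json")
  wj(list(treatment = as.list(disp$treatment),
          phenotype = as.list(disp$phenotype),
          interaction = as.list(disp$interaction)), "displacement.json")
  res$axis <- axis
  res$displacement <- disp

  wj(list(h2_true = ph$truth$h2_true, h2_realized = ph$truth$h2_realized,
          n_causal = length(ph$truth$causal),
          batch_offsets = as.list(batch_offsets),
          trajectory = as.list(truth_tc$params)), "truth.json")
  .write_pipeline_log(config, outdir)
  invisible(res)
}

## Deterministic run log: configuration, seed and package versions only
## (no timestamps, so runs with the same seed are byte-identical).
.write_pipeline_log <- function(config, outdir) {
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  lines <- c("rapasens pipeline run",
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("rapasens"))),
             sprintf("r_version: %s", R.version.string),
             sprintf("seed: %d", config$seed),
             sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
             "configuration:",
             paste0("  ", .flatten_config(config)))
  writeLines(lines, file.path(outdir, "log.txt"))
  invisible(NULL)
}
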