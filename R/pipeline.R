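#' Default demonstration configuration
#'
#' Configuration for [run_demo()]: study-scale segregant numbers (864
#' screened, 45 selected poor growers, 192 random controls, 5 replicate
#' phenotype measurements) with a reduced breeding program (3 lineages per
#' parent, 96 progeny per backcross round) so the whole chain runs in
#' about a minute. All stages draw from one RNG stream seeded with `seed`.
#'
#' @param seed integer seed recorded in every output.
#' @return Configuration list.
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    map = list(snp_spacing = 200, cm_per_kb = 0.4),
    program = list(n_f2 = 112, n_progeny_per_backcross = 96,
                   n_backcross_rounds = 6, n_lineages_per_parent = 3,
                   selection_quantile = 0.05),
    nil = list(halfwidth = 15000),
    f2b7 = list(n_screen = 864, n_selected = 45, n_controls = 192,
                n_replicates = 5),
    sequencing = list(nil_depth = 21, segregant_depth = 5,
                      base_error = 0.002),
    hmm = list(p_stay = 0.9999, epsilon = 0.05),
    mapping = list(min_count = 2, marker_halfwidth = 15000,
                   jaccard_min = 0.9, aneuploidy_threshold = 1.5),
    enrichment = list(p_hit = 1e-4),
    dosage_loci = c("L_I", "L_VII", "L_X1", "L_X2")
  )
}

# The calibrated noise SD is the residual SD of the *analysed* phenotype
# (the per-strain median of n replicates). Per-replicate noise is therefore
# inflated by 1/sqrt(var factor of the median of n standard normals):
# exact-ish factors for small odd n, asymptotic pi/(2n) otherwise.
median_noise_inflation <- function(n_replicates) {
  factors <- c(`1` = 1, `3` = 0.4487, `5` = 0.2868, `7` = 0.2104)
  f <- factors[as.character(n_replicates)]
  if (is.na(f)) f <- pi / (2 * n_replicates)
  1 / sqrt(f)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end demonstration pipeline on synthetic data
#'
#' Chains every component of the package on simulator output: breeding of
#' NILs by recurrent backcrossing with selection; NIL genotyping by
#' simulated low-coverage sequencing and HMM decoding with aneuploidy and
#' replicate screens; recurrence mapping of introgressed regions; a
#' selected-versus-control segregant screen with per-locus Fisher
#' enrichment and candidate-interval refinement; and per-condition
#' full-factorial ANOVA with the cross-condition additive effect profile.
#' Writes TSV/BED/JSON outputs stamped with the seed and configuration
#' fingerprint, and returns a machine-readable report comparing recovered
#' to configured parameters. Two runs with the same configuration produce
#' byte-identical outputs.
#'
#' @param config configuration list (see [demo_config()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return The report list, invisibly; also written to
#'   `<out_dir>/report.json`.
#' @export
run_demo <- function(config = demo_config(), out_dir = tempfile("nilmap_"),
                     quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  fp <- config_fingerprint(config)
  set.seed(seed)

  say("[setup] building map and calibrated phenotype model")
  map <- with_stage("setup", yeast_map(config$map$snp_spacing,
                                       config$map$cm_per_kb))
  model <- with_stage("setup", calibrate_phenotype_model(map))
  by <- parental_genotype(map, 0L)
  yjm <- parental_genotype(map, 1L)

  say("[breed] recurrent backcrossing with selection")
  program <- cross_program(
    n_f2 = config$program$n_f2,
    n_progeny_per_backcross = config$program$n_progeny_per_backcross,
    n_backcross_rounds = config$program$n_backcross_rounds,
    n_lineages_per_parent = config$program$n_lineages_per_parent,
    selection = selection_rule("E37", "bottom_quantile",
                               config$program$selection_quantile))
  bc <- with_stage("breed",
                   run_backcross_program(by, yjm, program, model, map))

  say("[genotype] sequencing and HMM decoding of ", length(bc$nils),
      " NILs")
  params <- hmm_params(p_stay = config$hmm$p_stay,
                       epsilon = config$hmm$epsilon)
  nil_sets <- with_stage("genotype", lapply(bc$nils, function(nl) {
    obs <- simulate_read_observations(nl$genotype, map,
                                      config$sequencing$nil_depth,
                                      config$sequencing$base_error)
    call_introgressions(obs, strain = nl$segments$strain,
                        background_allele = nl$background_allele,
                        params = params,
                        aneuploidy_threshold =
                          config$mapping$aneuploidy_threshold)
  }))
  aneuploid <- vapply(nil_sets, function(s)
    length(s$aneuploid_chroms) > 0, logical(1))
  kept <- nil_sets[!aneuploid]
  reps <- find_replicate_nils(kept, config$mapping$jaccard_min)
  if (nrow(reps)) kept <- kept[!names(kept) %in% reps$strain2]

  say("[map-loci] recurrence mapping over ", length(kept), " NILs")
  regions <- with_stage("map-loci", count_region_overlaps(kept))
  recurrent <- with_stage("map-loci", recurrent_loci(
    regions, config$mapping$min_count,
    marker_regions(map, config$mapping$marker_halfwidth)))

  say("[screen] F2B7 selection screen and control panel")
  nil3 <- synthetic_nil_genotype(map, halfwidth = config$nil$halfwidth)
  scr <- with_stage("screen", simulate_f2b7_population(
    nil3, yjm, config$f2b7$n_screen, map))
  causal_ids <- map$snp$id[locus_snp_indices(map, model$loci)]
  phen_scr <- simulate_phenotype_at_loci(
    scr$genotypes[, causal_ids, drop = FALSE], "E37", model)
  sel_idx <- order(phen_scr)[seq_len(config$f2b7$n_selected)]
  ctl <- with_stage("screen", simulate_f2b7_population(
    nil3, yjm, config$f2b7$n_controls, map))

  say("[enrich] genotyping ", length(sel_idx),
      " selected segregants and testing enrichment")
  sel_sets <- vector("list", length(sel_idx))
  sel_geno <- matrix(NA_integer_, length(sel_idx), ncol(scr$genotypes),
                     dimnames = list(NULL, colnames(scr$genotypes)))
  for (k in seq_along(sel_idx)) {
    g_full <- expand_f2b7_genotype(scr$genotypes[sel_idx[k], ],
                                   scr$poly_idx, yjm)
    obs <- simulate_read_observations(g_full, map,
                                      config$sequencing$segregant_depth,
                                      config$sequencing$base_error)
    st <- call_introgressions(obs, strain = sprintf("F2B7_sel_%02d", k),
                              background_allele = 1L, params = params)
    sel_sets[[k]] <- st
    sel_geno[k, ] <- attr(st, "states")[scr$poly_idx]
  }
  test_loci <- map$loci[map$loci$name != "MAT", , drop = FALSE]
  enrich <- with_stage("enrich", do.call(rbind, lapply(
    seq_len(nrow(test_loci)), function(i) {
      loc <- list(name = test_loci$name[i], chrom = test_loci$chrom[i],
                  start_bp = test_loci$pos[i] - config$nil$halfwidth,
                  end_bp = test_loci$pos[i] + config$nil$halfwidth)
      locus_enrichment(loc, sel_geno, ctl$genotypes, map$snp)
    })))
  enrich$role <- test_loci$role[match(enrich$locus, test_loci$name)]

  say("[refine] candidate intervals at significant causal loci")
  hits <- enrich$locus[enrich$p_value < config$enrichment$p_hit]
  refined <- with_stage("refine", do.call(rbind, lapply(
    intersect(hits, model$loci$name), function(nm) {
      i <- match(nm, map$loci$name)
      loc <- list(chrom = map$loci$chrom[i],
                  start_bp = map$loci$pos[i] - config$nil$halfwidth,
                  end_bp = map$loci$pos[i] + config$nil$halfwidth)
      # under an additive architecture a selected strain need not carry
      # the sensitive allele at every locus; only carriers constrain the
      # interval
      carriers <- Filter(function(s) {
        seg <- s$segments
        any(seg$chrom == loc$chrom & seg$allele == 0L &
              seg$start_bp <= map$loci$pos[i] &
              seg$end_bp >= map$loci$pos[i])
      }, sel_sets)
      if (length(carriers) < 2) return(NULL)
      iv <- refine_interval(loc, carriers)
      data.frame(locus = nm, chrom = loc$chrom,
                 start_bp = iv[["start_bp"]], end_bp = iv[["end_bp"]],
                 width_bp = iv[["end_bp"]] - iv[["start_bp"]] + 1L,
                 contains_locus = map$loci$pos[i] >= iv[["start_bp"]] &
                   map$loci$pos[i] <= iv[["end_bp"]],
                 stringsAsFactors = FALSE)
    })))

  say("[anova] replicate phenotyping and variance partitioning")
  ctl_causal <- ctl$genotypes[, causal_ids, drop = FALSE]
  colnames(ctl_causal) <- model$loci$name
  strains <- sprintf("F2B7_ctl_%03d", seq_len(nrow(ctl_causal)))
  rep_model <- model
  rep_model$noise_sd <- model$noise_sd *
    median_noise_inflation(config$f2b7$n_replicates)
  meas <- with_stage("anova", do.call(rbind, lapply(
    model$conditions, function(cn) {
      do.call(rbind, lapply(seq_len(config$f2b7$n_replicates),
                            function(r) {
        data.frame(strain = strains, replicate = r, condition = cn,
                   intensity = simulate_phenotype_at_loci(ctl_causal, cn,
                                                          rep_model),
                   stringsAsFactors = FALSE)
      }))
    })))
  medians <- aggregate_replicates(meas)
  tabs <- lapply(model$conditions, function(cn) {
    full_factorial_anova(medians[[paste0(cn, "_med")]], ctl_causal)
  })
  names(tabs) <- model$conditions
  profile <- condition_effect_profile(tabs)
  gvs <- genetic_variance_summary(tabs[["E37"]])
  dosage <- ctl$genotypes[, map$snp$id[locus_snp_indices(
    map, map$loci[match(config$dosage_loci, map$loci$name), ])],
    drop = FALSE]
  dose_fits <- lapply(model$conditions, function(cn)
    equal_effects_fit(medians[[paste0(cn, "_med")]], dosage))
  names(dose_fits) <- model$conditions

  say("[write] outputs to ", out_dir)
  w <- function(x, f) write_tsv(x, file.path(out_dir, f), seed, config)
  write_segments_bed(kept, file.path(out_dir, "nil_segments.bed"), seed,
                     config)
  w(regions, "regions.tsv")
  w(recurrent, "recurrent_loci.tsv")
  w(enrich, "enrichment.tsv")
  if (!is.null(refined)) w(refined, "refined_intervals.tsv")
  for (cn in model$conditions)
    w(as.data.frame(tabs[[cn]]), paste0("anova_", cn, ".tsv"))
  w(data.frame(condition = names(profile$mean_additive_pve),
               mean_additive_pve = unname(profile$mean_additive_pve)),
    "effect_profile.tsv")
  write_s8_table(medians, ctl_causal,
                 file.path(out_dir, "median_phenotypes.tsv"), seed, config)

  causal_names <- model$loci$name
  report <- list(
    tool = "nilmap", version = nilmap_version(), seed = seed,
    config_hash = fp,
    nils = list(n_bred = length(bc$nils), n_aneuploid = sum(aneuploid),
                n_replicate_dropped = nrow(reps), n_kept = length(kept),
                n_regions = nrow(regions),
                n_recurrent = nrow(recurrent)),
    enrichment = list(
      causal_hits = sort(intersect(hits, causal_names)),
      null_hits = sort(setdiff(hits, causal_names)),
      p_values = stats::setNames(enrich$p_value, enrich$locus)),
    refined_intervals = if (is.null(refined)) list() else refined,
    variance_partition = list(
      e37 = list(r2_g = gvs$r2_g, additive_share = gvs$additive_share,
                 main_pve = stats::setNames(
                   pve(tabs[["E37"]])[seq_len(nrow(model$loci))],
                   tabs[["E37"]]$term[seq_len(nrow(model$loci))])),
      profile = profile$mean_additive_pve,
      profile_monotone = profile$monotone,
      dosage_p = vapply(dose_fits, function(f) f$p_value, numeric(1))),
    configured = list(
      expected_pve_e37 = as.numeric(expected_pve(model, "E37")),
      severity = as.numeric(model$severity),
      beta = model$loci$beta))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
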