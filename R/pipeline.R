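#' Read a plain key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values holding
#' comma-separated numbers become numeric vectors. Unknown keys are a
#' usage error, so typos fail loudly.
#'
#' @param path Path to the config file.
#' @return Named list merged over the defaults of [default_run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_run_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(cfg))
      stop("unknown config field: '", key, "'")
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    cfg[[key]] <- if (all(!is.na(num))) num else val
  }
  cfg
}

#' Default run configuration
#'
#' Thresholds follow the package's standard workflow defaults:
#' reproducibility > 0.96, locus missingness <= 20%, sample missingness
#' <= 50%, common-locus MAF > 2%, clone threshold 0.4, propagation sizes
#' 16-64 by 4, translocation sizes 64-320 by 64, spatial thresholds
#' kinship >= 0.12 within 25 m (far = beyond 50 m).
#'
#' @return Named list of configuration fields.
#' @export
default_run_config <- function() {
  list(
    input = "", format = "dart_csv", sample_meta = "",
    preset = "pimelea_like",
    reproducibility_min = 0.96, missing_max = 0.20,
    sample_missing_max = 0.50, maf_min = 0.02,
    kinship_threshold = 0.4, min_shared = 50,
    np_sizes = seq(16, 64, by = 4), n_select = 36,
    nt_values = c(64, 128, 192, 256, 320),
    n_random_reps = 100, n_replicates = 100, generations = 10,
    selfing_rate = 0,
    sa_cool = 0.95, sa_swaps_per_temp = 100, sa_max_temps = 200,
    sa_max_rejects = 2000,
    clump_size = 5, clump_spacing = 30, within_spacing = 3,
    kin_min = 0.12, dist_max = 25, far_min = 50,
    n_null = 1000,
    seed = 1)
}

.cfg_cooling <- function(cfg) {
  sa_cooling(cool = cfg$sa_cool, swaps_per_temp = cfg$sa_swaps_per_temp,
             max_temps = cfg$sa_max_temps, max_rejects = cfg$sa_max_rejects)
}

.write_log <- function(out_dir, subcommand, cfg) {
  flat <- vapply(cfg, function(v) paste(v, collapse = ","), character(1))
  log <- c(sprintf("# exsitu %s | %s", as.character(utils::packageVersion("exsitu")),
                   subcommand),
           paste0(names(flat), " = ", flat))
  writeLines(log, file.path(out_dir, paste0(subcommand, ".log")))
}

.load_input <- function(cfg) {
  if (!nzchar(cfg$input))
    stop("config field 'input' is required for this subcommand")
  if (!file.exists(cfg$input))
    stop("input file not found: ", cfg$input,
         " (run the upstream subcommand first)")
  sm <- if (nzchar(cfg$sample_meta)) cfg$sample_meta else NULL
  read_genotypes(cfg$input, format = cfg$format, sample_meta = sm)
}

# filter -> kinship-prune -> complete-data common-locus matrix
.prepare_condemned <- function(g, cfg) {
  g <- filter_loci(g, cfg$reproducibility_min, cfg$missing_max)
  g <- remove_high_missing_samples(g, cfg$sample_missing_max)
  k <- estimate_kinship(g, min_shared = cfg$min_shared)
  groups <- similar_groups(k, cfg$kinship_threshold, n_missing = g)
  g <- prune_similar(g, groups)
  local_ids <- g$sample_meta$sample_id[
    !is.na(g$sample_meta$is_local) & g$sample_meta$is_local &
      !(g$sample_meta$is_hybrid %in% TRUE)]
  gl <- subset_geno(g, samples = local_ids)
  gl <- filter_loci(gl, reproducibility_min = NULL, missing_max = NULL,
                    require_complete = TRUE)
  ref <- common_loci(gl, maf_min = cfg$maf_min)
  list(pruned = g, condemned = subset_geno(gl, loci = ref),
       reference_common = ref, groups = groups)
}

#' Run a workflow stage
#'
#' Subcommands mirror the stages of the design workflow:
#' \describe{
#'   \item{simulate-data}{Generate a preset synthetic dataset and write it
#'     (dosage table, sample metadata, ground truth) under `out_dir`.}
#'   \item{filter}{Locus quality filters plus high-missingness sample
#'     removal; writes the filtered dosage table and filter report.}
#'   \item{kinship}{Kinship matrix, similar groups at the configured
#'     threshold, and the pruned matrix.}
#'   \item{design}{Chains filter, kinship pruning and the size sweep of
#'     optimized vs random propagation populations; writes the capture
#'     table, designs and nestedness matrix.}
#'   \item{supplement}{Multiobjective (diversity vs local representation)
#'     trade-off front for a collection supplemented with nonlocal
#'     individuals.}
#'   \item{arrange}{Spatial arrangement of an optimized collection on a
#'     clumped layout plus random-arrangement nulls.}
#'   \item{amplify}{Chains design and the translocation simulation grid
#'     over `np_sizes` subset x `nt_values`.}
#' }
#' Every stage writes tab-separated artifacts plus a `<subcommand>.log`
#' recording all parameters and seeds, so a run can be reproduced from its
#' log.
#'
#' @param subcommand One of the stages above.
#' @param config A config list ([default_run_config()] /
#'   [read_run_config()]) or a path to a config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the stage's main results.
#' @export
run_pipeline <- function(subcommand = c("simulate-data", "filter", "kinship",
                                        "design", "supplement", "arrange",
                                        "amplify"),
                         config = default_run_config(), out_dir = ".") {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  .write_log(out_dir, subcommand, cfg)

  if (subcommand == "simulate-data") {
    sim <- condemned_scenario(cfg$preset, seed = cfg$seed)
    write_genotypes(sim$genotypes, file.path(out_dir, "genotypes.csv"),
                    format = "dart_csv")
    utils::write.table(sim$genotypes$sample_meta,
                       file.path(out_dir, "sample_meta.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_ground_truth(sim$truth, file.path(out_dir, "truth"))
    return(invisible(sim))
  }

  g <- .load_input(cfg)

  if (subcommand == "filter") {
    gf <- filter_loci(g, cfg$reproducibility_min, cfg$missing_max)
    rep <- filter_report(gf)
    gf <- remove_high_missing_samples(gf, cfg$sample_missing_max)
    write_genotypes(gf, file.path(out_dir, "filtered.csv"),
                    format = "dart_csv")
    write_filter_report(rep, file.path(out_dir, "filter_report.tsv"))
    return(invisible(list(genotypes = gf, report = rep)))
  }

  if (subcommand == "kinship") {
    k <- estimate_kinship(g, min_shared = cfg$min_shared)
    groups <- similar_groups(k, cfg$kinship_threshold, n_missing = g)
    pruned <- prune_similar(g, groups)
    write_kinship(k, file.path(out_dir, "kinship.tsv"))
    write_groups(groups, file.path(out_dir, "similar_groups.tsv"),
                 stats::setNames(g$sample_meta$n_missing,
                                 g$sample_meta$sample_id))
    write_genotypes(pruned, file.path(out_dir, "pruned.csv"),
                    format = "dart_csv")
    return(invisible(list(kinship = k, groups = groups, pruned = pruned)))
  }

  prep <- .prepare_condemned(g, cfg)
  cooling <- .cfg_cooling(cfg)

  if (subcommand == "design") {
    gd <- prep$condemned
    sizes <- cfg$np_sizes[cfg$np_sizes <= nrow(gd$calls)]
    sweep <- size_sweep(gd, sizes = sizes,
                        reference_common = prep$reference_common,
                        cooling = cooling, n_random_reps = cfg$n_random_reps)
    nest <- nestedness(sweep$designs)
    write_metrics(sweep$table, file.path(out_dir, "capture_by_size.tsv"))
    write_designs(sweep$designs, file.path(out_dir, "designs.tsv"))
    utils::write.table(
      data.frame(sample_id = rownames(nest$membership), nest$membership,
                 check.names = FALSE),
      file.path(out_dir, "nestedness.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    return(invisible(list(sweep = sweep, nestedness = nest, prep = prep)))
  }

  if (subcommand == "supplement") {
    # pools: local = condemned non-hybrid, nonlocal = everything else,
    # restricted to complete common loci across the joint pool
    sm <- prep$pruned$sample_meta
    keep <- !(sm$is_hybrid %in% TRUE)
    pool <- sm$sample_id[keep]
    gp <- subset_geno(prep$pruned, samples = pool)
    gp <- filter_loci(gp, reproducibility_min = NULL, missing_max = NULL,
                      require_complete = TRUE)
    smp <- gp$sample_meta
    local <- smp$sample_id[smp$is_local %in% TRUE]
    nonlocal <- smp$sample_id[!(smp$is_local %in% TRUE)]
    front <- multiobjective_front(gp, local, nonlocal,
                                  n_select = cfg$n_select,
                                  cooling = cooling)
    tab <- do.call(rbind, lapply(front, function(d)
      data.frame(n_nonlocal = d$n_nonlocal,
                 proportion_local = d$proportion_local,
                 gene_diversity = d$objective_value)))
    write_metrics(tab, file.path(out_dir, "tradeoff_front.tsv"))
    write_designs(front, file.path(out_dir, "front_designs.tsv"))
    return(invisible(list(front = front, table = tab)))
  }

  if (subcommand == "arrange") {
    gd <- prep$condemned
    n <- min(cfg$n_select, nrow(gd$calls))
    des <- optimize_subset(gd, n_select = n, cooling = cooling)
    k <- estimate_kinship(subset_geno(prep$pruned,
                                      samples = des$selected),
                          min_shared = cfg$min_shared)
    layout <- clumped_layout(n, clump_size = cfg$clump_size,
                             clump_spacing = cfg$clump_spacing,
                             within_spacing = cfg$within_spacing)
    arr <- anneal_arrangement(des$selected, layout, k, cooling = cooling)
    nulls <- null_arrangements(des$selected, layout, k,
                               n_reps = cfg$n_null, kin_min = cfg$kin_min,
                               dist_max = cfg$dist_max)
    write_arrangement(arr, file.path(out_dir, "arrangement.tsv"))
    writeLines(as.character(nulls$counts),
               file.path(out_dir, "null_close_pair_counts.txt"))
    return(invisible(list(arrangement = arr, nulls = nulls,
                          design = des, kinship = k)))
  }

  # amplify: design then simulate the translocation grid
  gd <- prep$condemned
  sizes <- cfg$np_sizes[cfg$np_sizes <= nrow(gd$calls)]
  designs <- lapply(sizes, function(np)
    optimize_subset(gd, n_select = np, cooling = cooling))
  names(designs) <- sizes
  grid <- design_grid(gd, designs, cfg$nt_values,
                      reference_common = prep$reference_common,
                      generations = cfg$generations,
                      selfing_rate = cfg$selfing_rate,
                      n_replicates = cfg$n_replicates,
                      seed = cfg$seed)
  write_grid(grid, file.path(out_dir, "retention_grid.tsv"))
  invisible(list(grid = grid, designs = designs))
}
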