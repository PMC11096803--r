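#' Read an ensemble manifest
#'
#' TSV with columns \code{tree_id}, \code{path}, \code{rooting}
#' (\code{"midpoint"}, \code{"none"}, or \code{"outgroup:<file>"} where the
#' file lists one outgroup tip per line). Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest TSV.
#' @return named list of rooted \code{phylo} objects.
#' @export
read_tree_manifest <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("tree_id", "path", "rooting")
  if (!all(need %in% names(df)))
    stopf("manifest needs columns: %s", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  trees <- list()
  for (i in seq_len(nrow(df))) {
    tp <- resolve(df$path[i])
    if (!file.exists(tp)) stopf("tree file not found: %s", df$path[i])
    tr <- parse_newick(paste(readLines(tp, warn = FALSE), collapse = ""))
    rt <- df$rooting[i]
    if (rt == "midpoint") {
      tr <- midpoint_root(tr)
    } else if (startsWith(rt, "outgroup:")) {
      ogf <- resolve(sub("^outgroup:", "", rt))
      if (!file.exists(ogf)) stopf("outgroup file not found: %s", ogf)
      tr <- root_with_outgroup(tr, readLines(ogf, warn = FALSE))
    } else if (rt != "none") {
      stopf("unknown rooting scheme '%s' for tree %s", rt, df$tree_id[i])
    }
    trees[[df$tree_id[i]]] <- tr
  }
  trees
}

validate_run_config <- function(cfg, base) {
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  req_file <- function(p, what) {
    rp <- resolve(p)
    if (!file.exists(rp)) stopf("config: %s file not found: %s", what, p)
    rp
  }
  out <- cfg
  if (!is.null(cfg$classify)) {
    out$classify$manifest <- req_file(cfg$classify$manifest, "tree manifest")
    if (!is.null(cfg$classify$seeds))
      out$classify$seeds <- req_file(cfg$classify$seeds, "seeds")
  }
  if (!is.null(cfg$congruence)) {
    out$congruence$virus <- req_file(cfg$congruence$virus, "virus tree")
    out$congruence$host <- req_file(cfg$congruence$host, "host cladogram")
    out$congruence$map <- req_file(cfg$congruence$map, "tip-host map")
  }
  if (!is.null(cfg$rbs)) {
    out$rbs$fasta <- req_file(cfg$rbs$fasta, "segment FASTA")
    out$rbs$gff <- req_file(cfg$rbs$gff, "segment GFF3")
  }
  th <- out$thresholds %||% list()
  th$min_support <- th$min_support %||% 80
  th$purity <- th$purity %||% 0.9
  th$window <- th$window %||% 24
  th$costs <- th$costs %||% c(0, 1, 1, 1)
  th$samples <- th$samples %||% 100
  if (th$min_support < 0 || th$min_support > 100) stopf("config: min_support outside [0,100]")
  if (th$purity <= 0 || th$purity > 1) stopf("config: purity outside (0,1]")
  if (length(th$costs) != 4L || any(th$costs < 0)) stopf("config: costs must be 4 non-negative numbers")
  out$thresholds <- th
  out$seed <- out$seed %||% 1L
  out
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline from a config file
#'
#' Orchestrates the three analyses — ensemble genus classification, virus-host
#' congruence (nPH85 + DTL reconciliation, optionally restricted to
#' animal-associated tips via the map's \code{host_category} column), and RBS
#' motif scanning — as configured in a YAML file, writing per-stage TSV/JSON
#' outputs plus a run manifest (package version, seed, config hash) into
#' \code{out_dir}. Every stage is optional; identical config + seed gives
#' byte-identical JSON reports.
#'
#' Config layout (all paths relative to the config file):
#' \preformatted{
#' seed: 1
#' thresholds: {min_support: 80, purity: 0.9, window: 24,
#'              costs: [0, 1, 1, 1], samples: 100}
#' classify:   {manifest: trees.tsv, seeds: seeds.tsv}   # seeds optional
#' congruence: {virus: v.nwk, host: h.nwk, map: map.tsv,
#'              categories: [Mammalian, Avian]}          # categories optional
#' rbs:        {fasta: segs.fasta, gff: segs.gff3, label: "Segment 1"}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named list (in
#'   which case paths resolve against the working directory).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the report list (also written as \code{report.json}).
#' @export
run_all <- function(config, out_dir = "picobirnatax_out") {
  if (is.character(config)) {
    cfg_path <- normalizePath(config)
    cfg <- yaml::read_yaml(cfg_path)
    base <- dirname(cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
  } else {
    cfg <- config
    base <- getwd()
    cfg_hash <- NA_character_
  }
  cfg <- validate_run_config(cfg, base)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds
  report <- list(seed = cfg$seed, thresholds = th, config_hash = cfg_hash,
                 package_version = as.character(utils::packageVersion("picobirnatax")))

  if (!is.null(cfg$classify)) {
    t0 <- Sys.time()
    trees <- read_tree_manifest(cfg$classify$manifest)
    stage_log("classify", "read %d tree(s)", length(trees))
    seeds <- if (!is.null(cfg$classify$seeds)) {
      read_seeds(cfg$classify$seeds)
    } else {
      detect_seeds(trees[[1L]], min_support = th$min_support)
    }
    ga <- classify_ensemble(trees, seeds, min_support = th$min_support,
                            purity = th$purity)
    write_tsv_plain(ga$assignments, file.path(out_dir, "assignments.tsv"))
    write_tsv_plain(ga$evidence, file.path(out_dir, "evidence.tsv"))
    cc <- core_counts(ga)
    write_tsv_plain(cc, file.path(out_dir, "core_counts.tsv"))
    report$classify <- list(
      n_trees = length(trees), n_seeds = length(seeds),
      n_assigned = sum(ga$assignments$genus != "unclassified"),
      n_unclassified = sum(ga$assignments$genus == "unclassified"),
      core_counts = stats::setNames(as.list(cc$n_core), cc$genus))
    stage_log("classify", "%d/%d tips assigned (%.1fs)",
              report$classify$n_assigned, nrow(ga$assignments),
              as.numeric(Sys.time() - t0, units = "secs"))
  }

  if (!is.null(cfg$congruence)) {
    t0 <- Sys.time()
    vt <- parse_newick(paste(readLines(cfg$congruence$virus, warn = FALSE), collapse = ""))
    ht <- parse_newick(paste(readLines(cfg$congruence$host, warn = FALSE), collapse = ""))
    map <- read_tip_host_map(cfg$congruence$map)
    cats <- cfg$congruence$categories
    if (!is.null(cats)) {
      if (!"host_category" %in% names(map))
        stopf("config requests category filtering but the map has no host_category column")
      keep <- map$virus_tip[map$host_category %in% cats]
      dropn <- sum(!vt$tip.label %in% keep)
      if (dropn > 0L) {
        stage_log("congruence", "restricting to %d tip(s) in categories [%s]; %d dropped",
                  length(intersect(vt$tip.label, keep)),
                  paste(cats, collapse = ", "), dropn)
        vt <- ape::keep.tip(vt, intersect(vt$tip.label, keep))
      }
      map <- map[map$virus_tip %in% vt$tip.label, , drop = FALSE]
    }
    np <- nph85(vt, ht, map, mode = "expanded-host-tree")
    costs <- do.call(event_costs, as.list(stats::setNames(
      as.numeric(th$costs), c("cospeciation", "transfer", "duplication", "loss"))))
    vt_bin <- if (ape::is.binary(vt)) vt else with_seed(cfg$seed, ape::multi2di(vt))
    rec <- reconcile_mpr(vt_bin, ht, map, costs = costs, seed = cfg$seed)
    el <- event_likelihoods(rec, n_samples = th$samples, seed = cfg$seed)
    per <- as.data.frame(el$per_sample)
    per$sample <- seq_len(nrow(per))
    write_tsv_plain(per[, c("sample", "cospeciation", "transfer",
                            "duplication", "loss")],
                    file.path(out_dir, "event_samples.tsv"))
    report$congruence <- list(
      n_virus_tips = ape::Ntip(vt), n_host_tips = ape::Ntip(ht),
      nph85 = np$distance, nph85_mode = np$mode,
      min_cost = rec$min_cost, mpr_count = rec$mpr_count,
      samples = th$samples,
      event_proportions = as.list(el$event_proportions[
        c("cospeciation", "transfer", "duplication", "loss")]))
    stage_log("congruence", "nPH85 %.4f, min cost %g over %g MPR(s) (%.1fs)",
              np$distance, rec$min_cost, rec$mpr_count,
              as.numeric(Sys.time() - t0, units = "secs"))
  }

  if (!is.null(cfg$rbs)) {
    t0 <- Sys.time()
    segs <- read_segments(cfg$rbs$fasta, cfg$rbs$gff,
                          cfg$rbs$label %||% "segments")
    n0 <- length(segs)
    segs <- filter_segments(segs, min_utr = th$window)
    if (length(segs) < n0)
      stage_log("rbs", "%d segment(s) dropped (short 5' UTR or no ORFs)", n0 - length(segs))
    ft <- frequency_table(segs, window = th$window)
    write_tsv_plain(as.data.frame(ft), file.path(out_dir, "rbs_frequency.tsv"))
    write_tsv_plain(attr(ft, "hits"), file.path(out_dir, "rbs_hits.tsv"))
    report$rbs <- lapply(seq_len(nrow(ft)), function(i) as.list(as.data.frame(ft)[i, ]))
    stage_log("rbs", "%d segment(s), %d ORF(s) scanned (%.1fs)",
              length(segs), sum(ft$n_orfs),
              as.numeric(Sys.time() - t0, units = "secs"))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- data.frame(
    key = c("package", "version", "seed", "config_hash", "date"),
    value = c("picobirnatax", report$package_version, as.character(cfg$seed),
              cfg_hash %||% NA_character_, format(Sys.Date())),
    stringsAsFactors = FALSE)
  write_tsv_plain(manifest, file.path(out_dir, "run_manifest.tsv"))
  invisible(report)
}
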