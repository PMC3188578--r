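# End-to-end pipeline runner: assemble -> classify -> network -> date,
# from a single config, with a run manifest and per-stage logging.

#' Read a pipeline run config
#'
#' YAML with fields: either `variants` (a TSV written by
#' [write_variants()]) or `pileups` (directory of per-sample pileup files,
#' `<sample>.pileup`) plus `ref_fasta`; `tree` (haplotree TSV);
#' `populations` (TSV with columns `sample`, `population`; optional);
#' `clocks` (YAML, optional; defaults to [default_clocks()]); `region`
#' (two integers, default 577 16023); `epsilon` (default 0);
#' `min_branches` (default 5); `min_depth` (default 2); `min_frac`
#' (default 0.75); `out_dir`.
#'
#' @param path YAML config path.
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(region = CODING_REGION, epsilon = 0, min_branches = 5L,
                   min_depth = 2L, min_frac = 0.75, out_dir = ".")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$variants) && is.null(cfg$pileups)) {
    stop("config must provide 'variants' or 'pileups'")
  }
  if (!is.null(cfg$pileups) && is.null(cfg$ref_fasta)) {
    stop("config field missing: ref_fasta (required with pileups)")
  }
  if (is.null(cfg$tree)) stop("config field missing: tree")
  cfg
}

#' Run the full pipeline
#'
#' Executes every stage the config enables and writes: per-sample calls
#' (`calls.tsv`), the haplogroup frequency table (`frequencies.tsv`, when
#' populations are given), the network (`network.graphml`, `edges.tsv`),
#' the cluster report (`clusters.tsv`), the age table (`ages.tsv`), the
#' consensus FASTA and variant table (when starting from pileups), and a
#' JSON run manifest with stage counts.
#'
#' @param config path to a YAML config or a list as from
#'   [read_run_config()].
#' @return invisibly, the result list of [analyze_haplotypes()] plus
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[mtlineage] ", ...)
  manifest <- list(package = as.character(utils::packageVersion("mtlineage")),
                   config = cfg[setdiff(names(cfg), "out_dir")])
  ref <- if (!is.null(cfg$ref_fasta)) read_reference(cfg$ref_fasta)
  if (!is.null(cfg$pileups)) {
    files <- list.files(cfg$pileups, pattern = "\\.pileup$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("assemble: no .pileup files in ",
                                  cfg$pileups)
    conss <- lapply(files, function(f) {
      sid <- sub("\\.pileup$", "", basename(f))
      assemble_consensus(parse_pileup(f), ref, sample_id = sid,
                         min_depth = cfg$min_depth, min_frac = cfg$min_frac)
    })
    vsets <- lapply(conss, variants_vs_reference, ref = ref)
    names(vsets) <- vapply(conss, `[[`, "", "sample_id")
    write_consensus_fasta(conss, file.path(cfg$out_dir, "consensus.fasta"))
    write_variants(vsets, file.path(cfg$out_dir, "variants.tsv"))
    manifest$assemble <- list(samples = length(vsets),
                              mean_ambiguous = mean(vapply(conss, `[[`, 0,
                                                           "n_ambiguous")))
    log_stage("assemble: ", length(vsets), " consensus sequences")
  } else {
    vsets <- read_variants(cfg$variants)
    log_stage("input: ", length(vsets), " variant sets")
  }
  tree <- load_haplotree(cfg$tree, ref = ref)
  populations <- NULL
  if (!is.null(cfg$populations)) {
    pdf <- utils::read.table(cfg$populations, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("sample", "population") %in% names(pdf))) {
      stop("populations file needs columns 'sample' and 'population'")
    }
    populations <- stats::setNames(pdf$population, pdf$sample)
    absent <- setdiff(names(vsets), names(populations))
    if (length(absent)) stop("classify: sample(s) missing from population ",
                             "map: ", paste(utils::head(absent, 3L),
                                            collapse = ", "))
  }
  clocks <- if (!is.null(cfg$clocks)) load_clocks(cfg$clocks) else
    default_clocks()
  res <- analyze_haplotypes(vsets, tree, ref, populations = populations,
                            clocks = clocks, region = cfg$region,
                            epsilon = cfg$epsilon,
                            min_branches = cfg$min_branches)
  utils::write.table(res$calls, file.path(cfg$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("classify: ", nrow(res$calls), " calls, ",
            length(unique(res$calls$haplogroup)), " haplogroups")
  if (!is.null(res$freq)) {
    write_frequency_table(res$freq,
                          file.path(cfg$out_dir, "frequencies.tsv"))
  }
  write_network(res$network, file.path(cfg$out_dir, "network.graphml"),
                file.path(cfg$out_dir, "edges.tsv"))
  write_clusters(res$clusters, file.path(cfg$out_dir, "clusters.tsv"))
  log_stage("network: ", igraph::vcount(res$network$graph), " nodes, ",
            length(res$clusters), " star clusters")
  utils::write.table(res$ages, file.path(cfg$out_dir, "ages.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("date: ", nrow(res$ages), " age estimates")
  manifest$classify <- list(samples = nrow(res$calls))
  manifest$network <- list(nodes = igraph::vcount(res$network$graph),
                           clusters = length(res$clusters))
  manifest$date <- list(estimates = nrow(res$ages))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
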