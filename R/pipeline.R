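#' Default pipeline configuration
#'
#' All tunables of the pipeline with their defaults. Any subset can be
#' overridden via [read_config()] or the `config` argument of
#' [run_pipeline()]; unknown keys are rejected.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    # alignment
    mode = "global", gap_open = 20, gap_extend = 0.5, end_gaps_free = TRUE,
    match = 5, mismatch = -4, null_replicates = 1L,
    # graph / clustering
    adjacency_norm = "max", k_max = 15L, kmeans_tol = 1e-6,
    kmeans_restarts = 50L, n_clusters = NA_integer_,
    # Peyrard-Bishop chain
    pb_k = 0.025, pb_rho = 2, pb_alpha = 0.35,
    pb_D_W = 0.05, pb_D_S = 0.075, pb_a_W = 4.2, pb_a_S = 6.9,
    # regular-region detection
    P_thr = 3.7, eps = 0.01, delta = 1e-4, region_tol = 0.3, min_len = 7L,
    # composition / TATA
    tata_window_start = -40L, tata_window_end = -19L,
    tata_exclusions = NA_character_,
    # catalogue / repeats
    top_k = 15L, overlap_rule = "contained",
    # misc
    allow_n = "drop", seed = 0L, sampling = "none"
  )
}

#' Read a key-value configuration file
#'
#' Plain `key = value` lines (also `key: value`); `#` starts a comment.
#' Values are parsed as numeric or logical where possible. Keys must be a
#' subset of [default_config()].
#'
#' @param path file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return full configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  parse_val <- function(v) {
    v <- trimws(v)
    if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  apply_kv <- function(cfg, key, val) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- val
    cfg
  }
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
      if (length(kv) < 2) stop("cannot parse config line: ", ln)
      cfg <- apply_kv(cfg, trimws(kv[1]),
                      parse_val(paste(kv[-1], collapse = ":")))
    }
  }
  for (key in names(overrides)) cfg <- apply_kv(cfg, key, overrides[[key]])
  cfg
}

.cfg_scheme <- function(cfg) {
  scoring_scheme(mode = cfg$mode, gap_open = cfg$gap_open,
                 gap_extend = cfg$gap_extend,
                 end_gaps_free = isTRUE(cfg$end_gaps_free),
                 match = cfg$match, mismatch = cfg$mismatch)
}

.cfg_pb <- function(cfg) {
  pb_params(k = cfg$pb_k, rho = cfg$pb_rho, alpha = cfg$pb_alpha,
            D_W = cfg$pb_D_W, D_S = cfg$pb_D_S,
            a_W = cfg$pb_a_W, a_S = cfg$pb_a_S)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full promoter analysis pipeline
#'
#' Orchestrates: sequence ingest (FASTA or in-memory records), optional
#' TATA-balanced subsampling, TATA labelling, all-vs-all alignment and
#' spectral clustering, per-cluster base composition, per-promoter
#' regular-region detection, per-cluster regular-sequence catalogues, and
#' (when an annotation is given) repeat-overlap statistics. All artifacts
#' are written as TSV under `out_dir` together with a JSON manifest
#' recording the configuration, seeds and a config hash; deterministic
#' stages are bit-reproducible for identical inputs and configuration.
#'
#' @param fasta path to a promoter FASTA file (alternative to `records`).
#' @param records named character vector of promoters (alternative to
#'   `fasta`).
#' @param repeats optional path to a RepeatMasker `.out` or BED file, or a
#'   pre-parsed intervals data.frame.
#' @param config named list of overrides over [default_config()], or a
#'   full config from [read_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results: `clustering`,
#'   `labels`, `tata`, `regions`, `catalogs`, `coverage`, `manifest`.
#' @export
run_pipeline <- function(fasta = NULL, records = NULL, repeats = NULL,
                         config = list(), out_dir = "promspec_run") {
  cfg <- if (setequal(names(config), names(default_config()))) config
         else read_config(NULL, overrides = config)
  if (is.null(records)) {
    if (is.null(fasta)) stop("supply either 'fasta' or 'records'")
    records <- read_fasta(fasta)
  } else records <- as_promoters(records)
  records <- resolve_n(records, action = cfg$allow_n, seed = cfg$seed)
  if (length(records) < 2) stop("need at least 2 promoters after filtering")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cat_obj <- tata_catalog(exclusions = if (is.na(cfg$tata_exclusions)) NULL
                                       else cfg$tata_exclusions,
                          window = c(cfg$tata_window_start,
                                     cfg$tata_window_end))
  tata <- tata_labels(records, cat_obj)

  if (cfg$sampling == "balanced") {
    set.seed(cfg$seed)
    by_lab <- split(tata$id, tata$label)
    nmin <- min(lengths(by_lab))
    keep <- unlist(lapply(by_lab, sample, size = nmin))
    records <- records[names(records) %in% keep]
    tata <- tata[tata$id %in% keep, ]
    message("balanced sampling: ", length(records), " promoters kept")
  }

  cl <- cluster_promoters(records, scheme = .cfg_scheme(cfg),
                          k_max = cfg$k_max, seed = cfg$seed,
                          tol = cfg$kmeans_tol,
                          restarts = cfg$kmeans_restarts,
                          K = if (is.na(cfg$n_clusters)) NULL
                              else cfg$n_clusters,
                          normalization = cfg$adjacency_norm,
                          null_replicates = cfg$null_replicates)
  labels <- data.frame(id = names(cl$labels), cluster = unname(cl$labels))
  .write_tsv(labels, file.path(out_dir, "labels.tsv"))
  .write_tsv(data.frame(index = seq_along(cl$eigenvalues),
                        eigenvalue = cl$eigenvalues),
             file.path(out_dir, "eigenvalues.tsv"))
  .write_tsv(merge(tata, labels, by = "id"),
             file.path(out_dir, "tata_labels.tsv"))

  pbp <- .cfg_pb(cfg)
  regions <- detect_regions_set(records, params = pbp, P_thr = cfg$P_thr,
                                eps = cfg$eps, delta = cfg$delta,
                                tol = cfg$region_tol,
                                min_len = cfg$min_len)
  .write_tsv(regions, file.path(out_dir, "regions.tsv"))
  regions_to_bed(regions, file.path(out_dir, "regions.bed"))

  rpt <- NULL
  if (!is.null(repeats)) {
    rpt <- if (is.data.frame(repeats)) repeats
           else if (grepl("\\.bed$", repeats, ignore.case = TRUE))
             read_repeat_bed(repeats)
           else read_repeatmasker(repeats)
  }

  catalogs <- list(); coverage <- list(); bca <- list()
  for (k in sort(unique(stats::na.omit(cl$labels)))) {
    ids <- names(cl$labels)[!is.na(cl$labels) & cl$labels == k]
    recs_k <- records[ids]
    bca[[as.character(k)]] <- cbind(cluster = k, base_composition(recs_k))
    reg_k <- regions[regions$promoter_id %in% ids, , drop = FALSE]
    catalogs[[as.character(k)]] <-
      cbind(cluster = k,
            region_catalog(reg_k, recs_k, repeats = rpt,
                           top_k = cfg$top_k,
                           overlap_rule = cfg$overlap_rule))
    if (!is.null(rpt)) {
      cov <- repeat_coverage(rpt[rpt$promoter_id %in% ids, , drop = FALSE],
                             recs_k)
      fam <- if (length(cov$family_pct)) names(cov$family_pct) else NA_character_
      fam_pct <- if (length(cov$family_pct)) unname(cov$family_pct) else NA_real_
      coverage[[as.character(k)]] <-
        data.frame(cluster = k, total_pct = cov$total_pct,
                   family = fam, family_pct = fam_pct)
    }
  }
  .write_tsv(do.call(rbind, bca), file.path(out_dir, "bca.tsv"))
  .write_tsv(do.call(rbind, catalogs), file.path(out_dir, "catalog.tsv"))
  if (length(coverage))
    .write_tsv(do.call(rbind, coverage),
               file.path(out_dir, "repeat_coverage.tsv"))

  manifest <- list(
    package = "promspec",
    version = as.character(utils::packageVersion("promspec")),
    n_promoters = length(records),
    K = cl$K, theta = cl$theta, seed = cfg$seed,
    config = cfg,
    config_hash = .config_hash(cfg),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(clustering = cl, labels = labels, tata = tata,
                 regions = regions, catalogs = catalogs,
                 coverage = coverage, manifest = manifest))
}

# order-independent hash of the effective configuration; a plain polynomial
# hash mod a Mersenne prime avoids a digest dependency
.config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), ""),
    sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
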