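#' Pipeline configuration
#'
#' Collects every numeric threshold used across the pipeline in one object.
#' Defaults follow the published protocol for repeat and recombination
#' screening in plant mitochondrial genomes: repeats of at least 50 bp at
#' above 85% identity are censused; conformation references carry 1000 bp of
#' flanking sequence; a long read supports a conformation when it aligns at
#' above 95% identity covering at least 200 bp of both repeat flanks; homology
#' annotation uses a BLAST e-value cutoff of 1e-6; repeat size classes split
#' at 100 bp and 1000 bp.
#'
#' @param min_repeat_len minimum repeat length in bp (default 50)
#' @param min_repeat_identity minimum percent identity of a repeat pair,
#'   exclusive bound (default 85)
#' @param flank_len flank length in bp for conformation references
#'   (default 1000)
#' @param read_support_identity minimum percent identity of a read-to-reference
#'   alignment, exclusive bound (default 95)
#' @param read_support_flank_cov minimum bp of each repeat flank the alignment
#'   must cover (default 200)
#' @param homology_evalue e-value cutoff for homology searches (default 1e-6)
#' @param size_class_bounds two-element numeric: small/medium and medium/large
#'   boundaries in bp (default c(100, 1000); 100 and 1000 belong to medium)
#' @param screen_identity percent identity above which an alternative
#'   conformation found in the genome is discarded (default 95)
#' @param screen_coverage fraction of the reference length a genomic match
#'   must span for the reference to be discarded (default 0.95)
#' @param seed_kmer k-mer length used to seed the repeat scan (default 12)
#' @param mismatch_penalty positive score penalty per mismatch in the repeat
#'   scan (match scores +1; default 4, so segments below 80% identity score
#'   negative and are never extended)
#' @param rng_seed integer seed recorded with results (default 1)
#' @return an object of class `pipeline_config` (a named list)
#' @export
pipeline_config <- function(min_repeat_len = 50,
                            min_repeat_identity = 85,
                            flank_len = 1000,
                            read_support_identity = 95,
                            read_support_flank_cov = 200,
                            homology_evalue = 1e-6,
                            size_class_bounds = c(100, 1000),
                            screen_identity = 95,
                            screen_coverage = 0.95,
                            seed_kmer = 12,
                            mismatch_penalty = 4,
                            rng_seed = 1) {
  stopifnot(
    min_repeat_len > 0, min_repeat_identity > 0, flank_len > 0,
    read_support_identity > 0, read_support_flank_cov > 0,
    homology_evalue > 0, length(size_class_bounds) == 2,
    size_class_bounds[1] < size_class_bounds[2],
    screen_identity > 0, screen_coverage > 0, seed_kmer > 1,
    mismatch_penalty > 0
  )
  structure(
    list(
      min_repeat_len = min_repeat_len,
      min_repeat_identity = min_repeat_identity,
      flank_len = flank_len,
      read_support_identity = read_support_identity,
      read_support_flank_cov = read_support_flank_cov,
      homology_evalue = homology_evalue,
      size_class_bounds = size_class_bounds,
      screen_identity = screen_identity,
      screen_coverage = screen_coverage,
      seed_kmer = seed_kmer,
      mismatch_penalty = mismatch_penalty,
      rng_seed = rng_seed
    ),
    class = "pipeline_config"
  )
}

#' Read a key=value configuration file into a pipeline_config
#'
#' Lines of the form `key = value`; `#` starts a comment; unknown keys are an
#' error. Values override [pipeline_config()] defaults.
#'
#' @param path path to a text file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- formals(pipeline_config)
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    val <- as.numeric(strsplit(trimws(kv[2]), "[,[:space:]]+")[[1]])
    if (anyNA(val)) stop("non-numeric value for config key: ", key)
    args[[key]] <- val
  }
  do.call(pipeline_config, args)
}
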