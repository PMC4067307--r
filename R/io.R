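# Persistence: FASTA-dialect population snapshots (self-describing via an
# embedded alphabet table), YAML run configuration, and CSV reports stamped
# with the configuration digest.
#
# Snapshot format: ";;"-prefixed header lines (format version, alphabet
# table, update stamp), then one record per organism:
#   >id|genotype|lineage|role|x|y|facing|age|resources|generation
#   <single-character-encoded genome>
# The ">" metadata fields make standard FASTA tools able to inspect the
# sequences while the round trip stays bit-exact.

SNAPSHOT_FORMAT <- "digiprey-snapshot-1"

#' Write / read a population snapshot file
#'
#' The round trip `read_snapshot(write_snapshot(s))` reproduces the
#' organism table exactly. Files embed the serialisation alphabet; a file
#' whose alphabet disagrees with the running package, or that contains
#' unknown characters or malformed records, is rejected with the offending
#' line number.
#'
#' @param snap A `pop_snapshot`.
#' @param path File path.
#' @param tab Instruction table.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot`
#'   returns a `pop_snapshot`.
#' @export
write_snapshot <- function(snap, path, tab = default_instructions()) {
  org <- snap$organisms
  if (is.null(org$group)) org$group <- NA_character_
  header <- c(
    paste0(";; format=", SNAPSHOT_FORMAT),
    paste0(";; clock=", snap$clock),
    paste0(";; alphabet=", paste(tab$char, collapse = "")),
    paste0(";; symbols=", paste(tab$symbol, collapse = ","))
  )
  recs <- character(0)
  if (nrow(org) > 0L) {
    flags <- paste0(ifelse(org$realized, "R", "-"),
                    ifelse(org$parent_realized, "P", "-"))
    heads <- sprintf(">%s|%s|%s|%s|%d|%d|%d|%d|%s|%d|%s",
                     org$id, org$genotype, org$lineage, org$role,
                     org$x, org$y, org$facing, org$age,
                     formatC(org$resources, format = "g", digits = 17),
                     org$generation, flags)
    heads <- ifelse(is.na(org$group), heads,
                    paste0(heads, "|", org$group))
    recs <- as.vector(rbind(heads, org$genome))
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path, tab = default_instructions()) {
  lines <- readLines(path)
  hdr <- grepl("^;;", lines)
  header <- lines[hdr]
  body <- lines[!hdr & nzchar(lines)]
  get_field <- function(key) {
    m <- grep(paste0("^;; ", key, "="), header, value = TRUE)
    if (length(m) != 1L) stop("snapshot header missing field: ", key)
    sub(paste0("^;; ", key, "="), "", m)
  }
  if (get_field("format") != SNAPSHOT_FORMAT)
    stop("unknown snapshot format: ", get_field("format"))
  if (get_field("alphabet") != paste(tab$char, collapse = ""))
    stop("snapshot alphabet disagrees with the instruction table")
  clock <- as.integer(get_field("clock"))
  if (length(body) %% 2L != 0L)
    stop("truncated snapshot: record starting at line ",
         which(!hdr & nzchar(lines))[length(body)], " lacks a sequence")
  if (length(body) == 0L) {
    return(as_snapshot(data.frame(genome = character(0),
                                  stringsAsFactors = FALSE)))
  }
  heads <- body[seq(1L, length(body), by = 2L)]
  seqs <- body[seq(2L, length(body), by = 2L)]
  bad <- which(!startsWith(heads, ">"))
  if (length(bad) > 0L)
    stop("malformed record header at snapshot record ", bad[1])
  fields <- strsplit(sub("^>", "", heads), "|", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 11L))
    stop("malformed record header at snapshot record ", which(nf < 11L)[1])
  pull <- function(k) vapply(fields, `[[`, "", k)
  flags <- pull(11L)
  org <- data.frame(
    id = as.integer(pull(1L)),
    genome = seqs,
    genotype = pull(2L),
    lineage = pull(3L),
    role = pull(4L),
    realized = substr(flags, 1L, 1L) == "R",
    parent_realized = substr(flags, 2L, 2L) == "P",
    x = as.integer(pull(5L)), y = as.integer(pull(6L)),
    facing = as.integer(pull(7L)), age = as.integer(pull(8L)),
    generation = as.integer(pull(10L)),
    resources = as.numeric(pull(9L)),
    group = ifelse(nf >= 12L, vapply(fields, function(f)
      if (length(f) >= 12L) f[[12L]] else NA_character_, ""),
      NA_character_),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(seqs)) decode_genome(seqs[k], tab)  # validates
  structure(list(organisms = org, clock = clock), class = "pop_snapshot")
}

#' Default run configuration
#'
#' The structured configuration document, with blocks `world`, `organism`,
#' `mutation`, `predation`, `phase` and `rng`. Every model constant is
#' present and named; [load_config()] rejects unknown keys.
#'
#' @param profile Passed to [experiment_profile()].
#' @return A nested list.
#' @export
default_config <- function(profile = "desk") {
  prof <- experiment_profile(profile)
  list(
    world = list(width = prof$grid, height = prof$grid,
                 regen_delay = 100L, view_range = 20L),
    organism = list(cycles_per_update = 30L, max_age_updates = 500L,
                    max_instr = 15000L, repro_resource_threshold = 10,
                    repro_min_age_updates = 100L),
    mutation = list(phase1 = list(p_sub = 0.25, p_ins = 0.05, p_del = 0.05),
                    phase2 = list(p_sub = 0.001, p_ins = 0.005,
                                  p_del = 0.005)),
    predation = list(attack_cost_cycles = 10L,
                     predator_gain_fraction = 0.10,
                     min_prey = prof$prey_level),
    phase = list(profile = profile,
                 phase1_updates = prof$phase1_updates,
                 phase2_updates = prof$phase2_updates,
                 prey_level = prof$prey_level,
                 competition_level = prof$competition_level,
                 assay_level = prof$assay_level,
                 replicates = prof$replicates,
                 conditioning_updates = prof$conditioning_updates,
                 trial_updates = prof$trial_updates,
                 sample_every = prof$sample_every),
    rng = list(seed = 1L)
  )
}

#' Load / save a run configuration
#'
#' YAML on disk. Loading validates the block structure against
#' [default_config()]: unknown blocks or keys are rejected, missing keys
#' fall back to the defaults of the configured profile.
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `load_config` returns the validated nested list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  profile <- raw$phase$profile %||% "desk"
  ref <- default_config(profile)
  bad_blocks <- setdiff(names(raw), names(ref))
  if (length(bad_blocks) > 0L)
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "))
  for (blk in names(raw)) {
    bad <- setdiff(names(raw[[blk]]), names(ref[[blk]]))
    if (length(bad) > 0L)
      stop("unknown key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "))
    for (k in names(raw[[blk]])) ref[[blk]][[k]] <- raw[[blk]][[k]]
  }
  ref
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Digest of a configuration
#'
#' MD5 of the canonical YAML serialisation; stamped into every output CSV
#' so results are traceable to the exact configuration that produced them.
#'
#' @param config A configuration list.
#' @return A hex digest string.
#' @export
config_digest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a CSV report stamped with the configuration digest
#'
#' Standard CSV with a single leading comment line
#' `# config_digest=<md5>` so every report names the configuration that
#' produced it. [read_report()] skips the stamp.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param config Configuration list used for the digest (optional).
#' @return The path, invisibly.
#' @export
write_report <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  digest <- if (!is.null(config)) config_digest(config) else "none"
  writeLines(paste0("# config_digest=", digest), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname new_event_log
#' @param path Output CSV path.
#' @param config Optional configuration for the digest stamp.
#' @export
write_event_log <- function(log, path, config = NULL) {
  write_report(event_log_df(log), path, config = config)
}
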