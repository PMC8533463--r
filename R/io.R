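# Readers and writers for the study's plain-text formats. All tables are TSV;
# gene sets use the standard GMT layout (set name, description, members).

#' Read a count matrix TSV
#'
#' Expects a header row of sample ids with the feature ids in the first
#' column. Duplicated sample columns are dropped keep-first with a warning
#' (as for repeated aliquots of the same case); negative or non-integer
#' entries are rejected with the offending feature named.
#'
#' @param path TSV file path.
#' @return Wide count tibble (`feature_id` + one column per sample).
#' @export
read_counts <- function(path) {
  hdr <- raw_header(path)
  if (length(hdr) < 2L || hdr[1] != "feature_id") {
    abort(paste0("malformed header in ", path,
                 ": first column must be 'feature_id'"))
  }
  tb <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, name_repair = "minimal")
  probs <- readr::problems(tb)
  if (nrow(probs) > 0L) {
    abort(paste0("parse error in ", path, " at line ", probs$row[1] + 1L,
                 ": ", probs$expected[1], " vs ", probs$actual[1]))
  }
  dup <- duplicated(names(tb))
  if (any(dup)) {
    warn(paste0("read_counts: dropped ", sum(dup),
                " duplicated sample column(s) in ", path, " (kept first)"))
    tb <- tb[!dup]
  }
  m <- as.matrix(tb[-1])
  if (any(!is.finite(m))) abort(paste0("missing or non-numeric counts in ", path))
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(paste0("negative or non-integer count in ", path,
                 " at feature ", tb$feature_id[bad[1, 1]],
                 " (file line ", bad[1, 1] + 1L, "), sample ",
                 colnames(m)[bad[1, 2]]))
  }
  if (anyDuplicated(tb$feature_id)) {
    abort(paste0("duplicated feature ids in ", path))
  }
  tb
}

# readr's read_tsv reads names like "x" twice as x...1/x...2; go through a
# raw header check instead so duplicate sample ids are detectable.
#' @noRd
raw_header <- function(path) {
  strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
}

#' Read a sample sheet (sample_id, group)
#' @param path TSV with columns `sample_id`, `group` (tumor/normal).
#' @return Tibble.
#' @export
read_samples <- function(path) {
  tb <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(tb))) {
    abort(paste0("sample sheet ", path, " needs columns sample_id, group"))
  }
  bad <- setdiff(unique(tb$group), c("tumor", "normal"))
  if (length(bad) > 0L) {
    abort(paste0("unknown group label(s) in ", path, ": ",
                 paste(bad, collapse = ", ")))
  }
  tb
}

#' Read a feature biotype table
#' @param path TSV with columns `feature_id`, `biotype`.
#' @return Tibble.
#' @export
read_biotypes <- function(path) {
  tb <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("feature_id", "biotype") %in% names(tb))) {
    abort(paste0("biotype table ", path, " needs columns feature_id, biotype"))
  }
  bad <- setdiff(unique(tb$biotype), c("mRNA", "lncRNA", "pseudogene", "miRNA"))
  if (length(bad) > 0L) {
    abort(paste0("unknown biotype(s) in ", path, ": ", paste(bad, collapse = ", ")))
  }
  tb
}

#' Read a miRNA-target interaction edge list
#'
#' TSV with columns `mirna_id`, `target_id`; duplicated edges collapse
#' silently (set semantics).
#'
#' @param path TSV file path.
#' @param mirna_ids Optional explicit miRNA universe (see
#'   [interaction_map()]).
#' @return An [interaction_map()].
#' @export
read_interactions <- function(path, mirna_ids = NULL) {
  tb <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("mirna_id", "target_id") %in% names(tb))) {
    abort(paste0("interaction table ", path, " needs columns mirna_id, target_id"))
  }
  if (nrow(tb) == 0L && is.null(mirna_ids)) {
    abort(paste0("empty interaction table: ", path))
  }
  interaction_map(tb, mirna_ids = mirna_ids)
}

#' Read a clinical survival table
#' @param path TSV with columns `sample_id`, `time` (>= 0), `event` (0/1).
#' @return Tibble.
#' @export
read_clinical <- function(path) {
  tb <- readr::read_tsv(path, col_types = "cdd", progress = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(tb))) {
    abort(paste0("clinical table ", path, " needs columns sample_id, time, event"))
  }
  if (any(!is.finite(tb$time)) || any(tb$time < 0)) {
    abort(paste0("invalid follow-up time in ", path))
  }
  if (!all(tb$event %in% c(0, 1))) {
    abort(paste0("event indicator must be 0/1 in ", path))
  }
  tb$event <- as.integer(tb$event)
  tb
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path GMT file path.
#' @return Tibble with columns `set_id`, `description` and list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort(paste0("empty GMT file: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    abort(paste0("malformed GMT line(s) in ", path,
                 ": need name, description and at least one member"))
  }
  tibble(
    set_id = vapply(parts, `[[`, character(1), 1L),
    description = vapply(parts, `[[`, character(1), 2L),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param gene_sets Tibble as returned by [read_gmt()].
#' @return `write_gmt()` returns `path` invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$set_id[i],
            if ("description" %in% names(gene_sets)) gene_sets$description[i] else "",
            gene_sets$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a synthetic study to a directory tree
#'
#' Lays out the study the way the readers expect it: top-level
#' `interactions.tsv`, `biotypes.tsv`, `gene_sets.gmt` and `truth_*.tsv`
#' tables, plus one subdirectory per cohort holding `gene_counts.tsv`,
#' `mirna_counts.tsv`, `samples.tsv` and `clinical.tsv`. All files are
#' plain text and byte-deterministic given the study.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$map$edges, file.path(dir, "interactions.tsv"))
  readr::write_tsv(study$biotypes, file.path(dir, "biotypes.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(study$truth$planted_triplets[
    c("sponge_id", "mrna_id", "mirna_id", "key", "shared", "cohort_set")],
    file.path(dir, "truth_triplets.tsv"))
  readr::write_tsv(study$truth$planted_de, file.path(dir, "truth_de.tsv"))
  readr::write_tsv(study$truth$planted_prognostic,
                   file.path(dir, "truth_prognostic.tsv"))
  for (co in study$cohorts) {
    cdir <- file.path(dir, co$label)
    dir.create(cdir, showWarnings = FALSE)
    readr::write_tsv(co$gene_counts, file.path(cdir, "gene_counts.tsv"))
    readr::write_tsv(co$mirna_counts, file.path(cdir, "mirna_counts.tsv"))
    readr::write_tsv(co$samples, file.path(cdir, "samples.tsv"))
    readr::write_tsv(co$clinical, file.path(cdir, "clinical.tsv"))
  }
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return List with `map`, `biotypes`, `gene_sets` and `cohorts` (named
#'   list of `gene_counts`, `mirna_counts`, `samples`, `clinical`); planted
#'   truth tables are attached under `truth` when present.
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("study directory not found: ", dir))
  cohort_dirs <- sort(list.dirs(dir, recursive = FALSE))
  cohorts <- lapply(cohort_dirs, function(cd) {
    list(
      label = basename(cd),
      gene_counts = read_counts(file.path(cd, "gene_counts.tsv")),
      mirna_counts = read_counts(file.path(cd, "mirna_counts.tsv")),
      samples = read_samples(file.path(cd, "samples.tsv")),
      clinical = read_clinical(file.path(cd, "clinical.tsv"))
    )
  })
  names(cohorts) <- basename(cohort_dirs)
  biotypes <- read_biotypes(file.path(dir, "biotypes.tsv"))
  mirna_universe <- biotypes$feature_id[biotypes$biotype == "miRNA"]
  out <- list(
    map = read_interactions(file.path(dir, "interactions.tsv"),
                            mirna_ids = mirna_universe),
    biotypes = biotypes,
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    cohorts = cohorts
  )
  truth_path <- file.path(dir, "truth_triplets.tsv")
  if (file.exists(truth_path)) {
    out$truth <- list(
      planted_triplets = readr::read_tsv(truth_path, col_types = "cccclc",
                                         progress = FALSE),
      planted_de = readr::read_tsv(file.path(dir, "truth_de.tsv"),
                                   col_types = "ccc", progress = FALSE),
      planted_prognostic = readr::read_tsv(file.path(dir, "truth_prognostic.tsv"),
                                           col_types = "ccc", progress = FALSE)
    )
  }
  out
}
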