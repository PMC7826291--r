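# Construct nomenclature, registry and tidy CSV readers/writers.
#
# Construct names follow the <length>T<positions> convention: a leading
# integer gives the oligo(dT) lattice length, "T" the base identity, and the
# trailing field the 1-based 2-AP probe position(s) counted from the 5' end
# ("21T9" = 21-mer, monomer probe at 9; "28T22,23" = 28-mer, dimer probe at
# 22-23; a bare "21T" is the unlabeled control).

#' Build a construct name from its fields
#'
#' @param length_nt Lattice length (nt).
#' @param probe_positions Probe positions (possibly empty).
#' @return Character name such as `"21T9"`, `"28T22,23"`, `"21T"`.
#' @export
construct_name <- function(length_nt, probe_positions = integer(0)) {
  paste0(length_nt, "T", paste(probe_positions, collapse = ","))
}

#' Parse a construct name
#'
#' Inverse of [construct_name()]: extracts lattice length, probe positions
#' and probe kind.  Two comma-separated positions must be adjacent (a dimer
#' probe); parsed fields round-trip to the original name.
#'
#' @param name Construct name, e.g. `"21T9"` or `"28T22,23"`.
#' @return A [lattice_construct].
#' @examples
#' parse_construct_name("21T9")
#' parse_construct_name("28T22,23")
#' @export
parse_construct_name <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !grepl("^[0-9]+T([0-9]+(,[0-9]+)?)?$", name)) {
    stop(sprintf("malformed construct name: '%s'", name), call. = FALSE)
  }
  parts <- regmatches(name, regexec("^([0-9]+)T([0-9,]*)$", name))[[1L]]
  length_nt <- as.integer(parts[2L])
  pos <- if (nzchar(parts[3L])) {
    as.integer(strsplit(parts[3L], ",", fixed = TRUE)[[1L]])
  } else integer(0)
  if (length(pos) == 2L && diff(pos) != 1L) {
    stop(sprintf("non-adjacent dimer positions in '%s'", name), call. = FALSE)
  }
  lattice_construct(length_nt, pos, name = name)
}

#' Registry of the standard construct set
#'
#' All constructs used in the footprinting design: 21-mer oligo(dT) lattices
#' with monomer 2-AP probes at positions 7-14, dimer-probe 21-mers at (8,9)
#' and (13,14), dimer-probe 28-mers at (8,9) and (22,23), and unlabeled
#' controls of both lengths.
#'
#' @return Named list of [lattice_construct] objects.
#' @export
construct_registry <- function() {
  names <- c(
    paste0("21T", 7:14),
    "21T8,9", "21T13,14", "28T8,9", "28T22,23",
    "21T", "28T"
  )
  stats::setNames(lapply(names, parse_construct_name), names)
}

#' Registry subsets
#'
#' Convenience selectors over [construct_registry()].
#'
#' @param kind One of `"monomer"`, `"dimer"`, `"none"`.
#' @return Character vector of construct names.
#' @export
registry_names <- function(kind = c("monomer", "dimer", "none")) {
  kind <- match.arg(kind)
  reg <- construct_registry()
  names(reg)[vapply(reg, function(x) x$probe_kind == kind, logical(1))]
}

#' Write a tidy table as CSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy CSV and validate its schema
#'
#' Rejects files whose header does not contain the required columns, naming
#' the missing columns, and reports rows with missing values in required
#' columns by line number.
#'
#' @param path Input CSV path.
#' @param required Character vector of required column names.
#' @return A data.frame.
#' @export
read_tidy_csv <- function(path, required = character(0)) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(required)) {
    bad <- which(!stats::complete.cases(df[required]))
    if (length(bad)) {
      stop(sprintf("%s: missing values in required columns at line(s) %s",
                   path, paste(utils::head(bad + 1L, 10L), collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}
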