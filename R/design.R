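#' Declare an oligo-library architecture
#'
#' A HISSA library is built from a partially randomized oligo whose layout is
#' fixed by the library design: an optional 5' UMI, a 5' linker anchor, a short
#' stretch of linker-randomized bases, the randomized variable region under
#' study, a constant insert tail (the non-variable 3' portion of the oligo,
#' here the mir-317 loop 3' end), and the 3' sequencing adapter. All structural
#' read filters are derived from this declaration.
#'
#' Reads are laid out 5' to 3' as
#' `[UMI][anchor5][linker_random][variable_region][constant_insert][adapter3]`.
#' Coordinates are 0-based half-open. All sequences are held in DNA space;
#' U on input is mapped to T.
#'
#' @param design_id label for the design.
#' @param umi_length UMI length in nt (0 when the design carries no UMI).
#' @param anchor5 5'-linker anchor sequence preceding the linker-randomized
#'   bases (empty string when the design declares no anchor).
#' @param linker_random_length number of randomized linker bases between the
#'   anchor and the variable region.
#' @param variable_length length of the randomized variable region under study.
#' @param constant_insert non-variable insert sequence expected immediately
#'   after the variable region.
#' @param adapter3 3' sequencing adapter.
#' @param required_anchor_gap enforced distance in nt between the end of
#'   `anchor5` and the start of `constant_insert`; must equal
#'   `linker_random_length + variable_length` when an anchor is declared.
#'   Defaults to that sum.
#' @param max_constant_mismatch maximum mismatches tolerated when matching
#'   `constant_insert` at its expected position (default 0, exact match).
#' @return validated object of class `oligo_design`.
#' @examples
#' d8 <- oligo_design("5p8N", umi_length = 12, anchor5 = "TGTAGC",
#'                    linker_random_length = 2, variable_length = 8,
#'                    constant_insert = "AATGCAAGCAAG")
#' d8$required_anchor_gap  # 10
#' @export
oligo_design <- function(design_id,
                         umi_length = 0L,
                         anchor5 = "",
                         linker_random_length = 0L,
                         variable_length,
                         constant_insert,
                         adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                         required_anchor_gap = NULL,
                         max_constant_mismatch = 0L) {
  stopifnot(is.character(design_id), length(design_id) == 1L)
  umi_length <- as.integer(umi_length)
  linker_random_length <- as.integer(linker_random_length)
  variable_length <- as.integer(variable_length)
  if (is.na(variable_length) || variable_length < 1L) {
    stop("variable_length must be >= 1")
  }
  if (is.na(umi_length) || umi_length < 0L) stop("umi_length must be >= 0")
  if (linker_random_length < 0L) stop("linker_random_length must be >= 0")
  anchor5 <- normalize_dna(anchor5)
  constant_insert <- normalize_dna(constant_insert)
  adapter3 <- normalize_dna(adapter3)
  for (field in c(anchor5 = anchor5, constant_insert = constant_insert,
                  adapter3 = adapter3)) {
    if (!is_valid_dna(field)) {
      stop("sequence fields must be drawn from {A,C,G,T} (U is mapped to T): ",
           field)
    }
  }
  if (nchar(constant_insert) < 1L) stop("constant_insert must be non-empty")
  gap <- linker_random_length + variable_length
  if (is.null(required_anchor_gap)) {
    required_anchor_gap <- gap
  } else if (nzchar(anchor5) && as.integer(required_anchor_gap) != gap) {
    stop(sprintf(
      "required_anchor_gap (%d) must equal linker_random_length + variable_length (%d)",
      as.integer(required_anchor_gap), gap))
  }
  structure(list(
    design_id = design_id,
    umi_length = umi_length,
    anchor5 = anchor5,
    linker_random_length = linker_random_length,
    variable_length = variable_length,
    constant_insert = constant_insert,
    constant_insert_offset = variable_length,
    adapter3 = adapter3,
    required_anchor_gap = as.integer(required_anchor_gap),
    max_constant_mismatch = as.integer(max_constant_mismatch)
  ), class = "oligo_design")
}

#' @export
print.oligo_design <- function(x, ...) {
  cat(sprintf(
    "oligo_design '%s': [UMI %dnt][%s][%dN linker][%dN variable][%s][adapter]\n",
    x$design_id, x$umi_length,
    if (nzchar(x$anchor5)) x$anchor5 else "-",
    x$linker_random_length, x$variable_length, x$constant_insert))
  invisible(x)
}

#' Built-in library designs
#'
#' Presets for the two library architectures used in fly Argonaute loading
#' assays: a 5-nt randomized design without UMI (constant tail
#' `TGAAATGCAAGCAAG`) and an 8-nt randomized design with a 12-nt UMI, the
#' `TGTAGC` 5'-linker anchor, two linker-randomized bases and constant tail
#' `AATGCAAGCAAG` (enforced anchor gap of 10 nt).
#'
#' @param name `"5N"` or `"8N"`.
#' @return `oligo_design`.
#' @export
hissa_design <- function(name = c("8N", "5N")) {
  name <- match.arg(name)
  switch(name,
    "5N" = oligo_design("5p5N", umi_length = 0L, anchor5 = "",
                        linker_random_length = 0L, variable_length = 5L,
                        constant_insert = "TGAAATGCAAGCAAG"),
    "8N" = oligo_design("5p8N", umi_length = 12L, anchor5 = "TGTAGC",
                        linker_random_length = 2L, variable_length = 8L,
                        constant_insert = "AATGCAAGCAAG")
  )
}

#' Load an oligo design from a structured config file
#'
#' The config is a `key = value` or `key: value` text file (one field per
#' line, `#` comments allowed) naming the fields of [oligo_design()].
#'
#' @param path config file path.
#' @return validated `oligo_design`.
#' @export
load_design <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  cfg <- stats::setNames(as.list(vals), keys)
  num_fields <- c("umi_length", "linker_random_length", "variable_length",
                  "required_anchor_gap", "max_constant_mismatch")
  for (f in intersect(names(cfg), num_fields)) {
    v <- suppressWarnings(as.integer(cfg[[f]]))
    if (is.na(v)) stop("field '", f, "' must be an integer, got: ", cfg[[f]])
    cfg[[f]] <- v
  }
  allowed <- c("design_id", "anchor5", "constant_insert", "adapter3", num_fields)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop("unknown design field(s): ",
                            paste(unknown, collapse = ", "))
  do.call(oligo_design, cfg)
}
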