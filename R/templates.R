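# Palindrome templates of the afe-box operator and combinatorial variant
# enumeration used to train the profile models.

WILDCARD_SETS <- list(
  N = c("A", "C", "G", "T"),
  Y = c("C", "T"),
  R = c("A", "G")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  N = "N", Y = "R", R = "Y"
)

MODEL_LETTERS <- c(SP13 = "A", SP15 = "B", MP18 = "C", MP20 = "D", LP30 = "E")
SET_LABELS    <- c(SP13 = "SP", SP15 = "SP", MP18 = "MP", MP20 = "MP",
                   LP30 = "LP")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] restricted to the
#' `A`, `C`, `G`, `T`, `N` alphabet. Vectorised over `seq`.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TGACA")  # "TGTCA"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("revcomp(): non-DNA character in sequence(s): ",
         paste(utils::head(seq[bad], 3L), collapse = ", "))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# reverse complement over the template alphabet (incl. Y/R wildcards)
iupac_revcomp <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(IUPAC_COMPLEMENT))) {
    stop("unsupported symbol in pattern: ", pattern)
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

new_palindrome_template <- function(id, pattern, arms, symmetry_center) {
  stopifnot(id %in% names(MODEL_LETTERS))
  tpl <- structure(
    list(
      id = id,
      model_id = unname(MODEL_LETTERS[[id]]),
      set_label = unname(SET_LABELS[[id]]),
      pattern = pattern,
      length = nchar(pattern),
      arms = arms,
      symmetry_center = symmetry_center
    ),
    class = "palindrome_template"
  )
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  chars <- strsplit(tpl$pattern, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N", "Y", "R"))) {
    stop("template pattern restricted to {A,C,G,T,N,Y,R}: ", tpl$pattern)
  }
  arms <- tpl$arms
  left  <- arms[arms$role == "arm_left", , drop = FALSE]
  right <- arms[arms$role == "arm_right", , drop = FALSE]
  stopifnot(nrow(left) == nrow(right))
  for (k in seq_len(nrow(left))) {
    l <- substr(tpl$pattern, left$start[k], left$end[k])
    r <- substr(tpl$pattern, right$start[k], right$end[k])
    rc <- iupac_revcomp(l)
    # compare at fixed (non-N) positions only
    lc <- strsplit(rc, "")[[1]]
    rcars <- strsplit(r, "")[[1]]
    fixed <- lc != "N" & rcars != "N"
    if (!all(lc[fixed] == rcars[fixed])) {
      stop("arm pair ", k, " of ", tpl$id, " is not dyad-symmetric")
    }
  }
  invisible(tpl)
}

#' @export
print.palindrome_template <- function(x, ...) {
  cat(sprintf("<palindrome_template %s (model %s, set %s)>\n  %s  (%d bp, center %.1f)\n",
              x$id, x$model_id, x$set_label, x$pattern, x$length,
              x$symmetry_center))
  invisible(x)
}

#' Built-in afe-box palindrome templates
#'
#' Returns the five palindrome templates derived from the modular structure of
#' the 30-bp afe-box operator upstream of `afeI`: two short palindromes (13 and
#' 15 bp, models A/B, set SP), two medium palindromes spanning the lux-box-like
#' core (18 and 20 bp, models C/D, set MP), and the full 30-bp large palindrome
#' (model E, set LP). Wildcards: `N` = any base, `Y` = pyrimidine, `R` =
#' purine. Fixed positions of each template's arm pair are exact reverse
#' complements of one another.
#'
#' @return Named list of `palindrome_template` objects
#'   (`SP13`, `SP15`, `MP18`, `MP20`, `LP30`).
#' @examples
#' tpls <- builtin_templates()
#' tpls$SP13$pattern
#' @export
builtin_templates <- function() {
  arms <- function(...) {
    df <- data.frame(matrix(c(...), ncol = 3L, byrow = TRUE))
    names(df) <- c("start", "end", "role")
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    df
  }
  list(
    SP13 = new_palindrome_template(
      "SP13", "TGACANNNTGTCA",
      arms(1, 5, "arm_left", 6, 8, "spacer", 9, 13, "arm_right"),
      symmetry_center = 7
    ),
    SP15 = new_palindrome_template(
      "SP15", "YTGACANNNTGTCAR",
      arms(1, 6, "arm_left", 7, 9, "spacer", 10, 15, "arm_right"),
      symmetry_center = 8
    ),
    MP18 = new_palindrome_template(
      "MP18", "GCTGTCAANNTTGACAGC",
      arms(1, 8, "arm_left", 9, 10, "spacer", 11, 18, "arm_right"),
      symmetry_center = 9.5
    ),
    MP20 = new_palindrome_template(
      "MP20", "AGCTGTCAANNTTGACAGCT",
      arms(1, 9, "arm_left", 10, 11, "spacer", 12, 20, "arm_right"),
      symmetry_center = 10.5
    ),
    LP30 = new_palindrome_template(
      "LP30", "TGACAAGCTGTCANNNNTGACAGCTTGTCA",
      arms(1, 13, "arm_left", 14, 17, "spacer", 18, 30, "arm_right"),
      symmetry_center = 15.5
    )
  )
}

#' Enumerate all variant sequences of a palindrome template
#'
#' Expands every wildcard position of the template combinatorially (`N` to the
#' four bases, `Y` to `C`/`T`, `R` to `A`/`G`) into the exhaustive,
#' duplicate-free set of matching sequences, in lexicographic order. These
#' fixed-length ungapped alignments are the training sets for
#' [build_profile()]: SP13 expands to 64 sequences, SP15 to 256, MP18 and MP20
#' to 16 each, and LP30 to 256.
#'
#' @param template A `palindrome_template` (or a raw pattern string over
#'   `{A,C,G,T,N,Y,R}`).
#' @return A `variant_alignment`: list with `template_id`, `sequences`
#'   (character vector) and `count`.
#' @examples
#' enumerate_variants(builtin_templates()$MP18)$count  # 16
#' @export
enumerate_variants <- function(template) {
  if (is.character(template) && length(template) == 1L) {
    pattern <- template
    id <- pattern
  } else {
    stopifnot(inherits(template, "palindrome_template"))
    pattern <- template$pattern
    id <- template$id
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", names(WILDCARD_SETS)))
  if (length(bad)) {
    stop("unknown wildcard symbol(s) in pattern: ", paste(bad, collapse = ", "))
  }
  choices <- lapply(chars, function(ch) {
    if (ch %in% names(WILDCARD_SETS)) WILDCARD_SETS[[ch]] else ch
  })
  grid <- expand.grid(rev(choices), stringsAsFactors = FALSE)[, rev(seq_along(choices)), drop = FALSE]
  seqs <- do.call(paste0, grid)
  seqs <- sort(unique(seqs), method = "radix")
  structure(
    list(template_id = id, sequences = seqs, count = length(seqs)),
    class = "variant_alignment"
  )
}

#' @export
print.variant_alignment <- function(x, ...) {
  cat(sprintf("<variant_alignment %s: %d sequences of %d bp>\n",
              x$template_id, x$count, nchar(x$sequences[1])))
  invisible(x)
}

#' Write a variant alignment as aligned FASTA
#'
#' @param alignment A `variant_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "variant_alignment"))
  dss <- Biostrings::DNAStringSet(alignment$sequences)
  names(dss) <- sprintf("%s_var%04d", alignment$template_id,
                        seq_along(alignment$sequences))
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Dump the built-in templates as a plain-text table
#'
#' @param templates List of templates, as from [builtin_templates()].
#' @param path Output TSV path (or `""` for stdout).
#' @return Data frame written, invisibly.
#' @export
write_template_table <- function(templates = builtin_templates(), path = "") {
  df <- do.call(rbind, lapply(templates, function(t) {
    data.frame(
      id = t$id, model_id = t$model_id, set_label = t$set_label,
      length = t$length, pattern = t$pattern,
      arms = paste(sprintf("%d-%d:%s", t$arms$start, t$arms$end, t$arms$role),
                   collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(df) <- NULL
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
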