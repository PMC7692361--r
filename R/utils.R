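# Shared helpers: intervals, sequences, seeds.

# All intervals are 0-based half-open [start, end) internally; GFF I/O
# converts to 1-based inclusive at the boundary.

interval_length <- function(start, end) end - start

stopifnot_scalar_sex <- function(sex) {
  if (!(is.character(sex) && length(sex) == 1L && sex %in% c("male", "female"))) {
    rlang::abort("`sex` must be \"male\" or \"female\"")
  }
  invisible(sex)
}

# Deterministic sub-seeds so each emitter is reproducible independently of
# call order. Offsets are fixed per stream; results stay below 2^31.
sub_seed <- function(seed, stream) {
  offsets <- c(
    reference = 11L, depth_female = 23L, depth_male = 29L,
    variants_female = 37L, variants_male = 41L, codon = 53L,
    expression = 61L, layout = 71L
  )
  if (!stream %in% names(offsets)) rlang::abort(paste0("unknown seed stream: ", stream))
  (as.integer(seed) * 1009L + offsets[[stream]]) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Standard genetic code keyed by codon string, e.g. CODON_TABLE[["ATG"]] == "M".
CODON_TABLE <- as.list(Biostrings::GENETIC_CODE)

translate_codons <- function(codons) {
  unlist(CODON_TABLE[codons], use.names = FALSE)
}

is_stop_codon <- function(codons) {
  translate_codons(codons) == "*"
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) rlang::abort("sequence length not divisible by 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# row-bind preserving zero-row case with a template of column types
bind_or_template <- function(rows, template) {
  if (length(rows) == 0L) template else dplyr::bind_rows(rows)
}
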