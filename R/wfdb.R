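# Minimal WFDB interchange: format-16 signal files with a plain-text header,
# MIT-format binary annotation files for beats, and a JSON-lines manifest for
# rhythm intervals and record-level labels (rhythm-annotation conventions
# vary across WFDB corpora, so rhythms live in the manifest). All sample
# indices on disk are 0-based; intervals are half-open.

WFDB_GAIN <- 200  # ADC units per signal unit
BEAT_CODE <- c(NORMAL = 1L, ABERRATION = 4L, PVC = 5L, PAC = 8L)
CODE_BEAT <- stats::setNames(names(BEAT_CODE), BEAT_CODE)

write_wfdb_signal <- function(signal, fs, record, dir, description = "ECG") {
  adc <- as.integer(pmin(32767, pmax(-32768, round(signal * WFDB_GAIN))))
  chks <- sum(adc) %% 65536
  if (chks > 32767) chks <- chks - 65536
  hea <- c(sprintf("%s 1 %g %d", record, fs, length(adc)),
           sprintf("%s.dat 16 %d 16 0 %d %d 0 %s", record, WFDB_GAIN,
                   if (length(adc)) adc[1] else 0, chks, description))
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  con <- file(file.path(dir, paste0(record, ".dat")), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(record, c(".hea", ".dat"))))
}

read_wfdb_signal <- function(path_base) {
  hea_path <- paste0(path_base, ".hea")
  if (!file.exists(hea_path)) stop("missing WFDB header: ", hea_path)
  hea <- readLines(hea_path)
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  fs <- as.numeric(top[3]); n <- as.integer(top[4])
  sig_line <- strsplit(trimws(hea[2]), "\\s+")[[1]]
  gain <- as.numeric(sig_line[3])
  dat_path <- file.path(dirname(hea_path), sig_line[1])
  if (!file.exists(dat_path)) stop("missing WFDB signal file: ", dat_path)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  adc <- readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little")
  if (length(adc) != n) stop("signal file ", dat_path, " shorter than header declares")
  list(signal = adc / gain, fs = fs, n = n)
}

# MIT annotation format: 16-bit little-endian words, annotation type in the
# high 6 bits, time increment (samples since previous annotation) in the low
# 10 bits. Increments above 1023 are written as a SKIP (code 59) pseudo-
# annotation followed by a 4-byte increment (most significant 16-bit word
# first); the annotation word that follows then carries increment 0.
write_wfdb_annotations <- function(beats, record, dir) {
  path <- file.path(dir, paste0(record, ".atr"))
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  words <- integer(0)
  for (i in seq_len(nrow(beats))) {
    code <- BEAT_CODE[[beats$class[i]]]
    delta <- beats$sample[i] - prev
    if (delta > 1023L) {
      words <- c(words, bitwShiftL(59L, 10L),
                 delta %/% 65536L, delta %% 65536L)
      delta <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(code, 10L), delta))
    prev <- beats$sample[i]
  }
  words <- c(words, 0L)
  words[words > 32767L] <- words[words > 32767L] - 65536L
  writeBin(as.integer(words), con, size = 2, endian = "little")
  invisible(path)
}

read_wfdb_annotations <- function(path_base) {
  path <- paste0(path_base, ".atr")
  if (!file.exists(path)) stop("missing WFDB annotation file: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  words <- readBin(con, "integer", n = sz %/% 2, size = 2, signed = FALSE,
                   endian = "little")
  sample <- integer(0); cls <- character(0)
  t <- 0L; i <- 1L; pending_skip <- 0L
  while (i <= length(words)) {
    w <- words[i]
    if (w == 0L) break
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (code == 59L) {
      if (i + 2L > length(words)) stop("truncated SKIP in ", path)
      pending_skip <- words[i + 1L] * 65536L + words[i + 2L]
      i <- i + 3L
      next
    }
    t <- t + delta + pending_skip
    pending_skip <- 0L
    if (!as.character(code) %in% names(CODE_BEAT))
      stop("unknown beat annotation code '", code, "' in ", path)
    sample <- c(sample, t)
    cls <- c(cls, CODE_BEAT[[as.character(code)]])
    i <- i + 1L
  }
  data.frame(sample = sample, class = cls, stringsAsFactors = FALSE)
}

manifest_path <- function(dir) file.path(dir, "manifest.jsonl")

append_manifest <- function(dir, entry) {
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = manifest_path(dir), append = TRUE)
  invisible(entry)
}

#' Read the JSON-lines manifest of a corpus directory
#' @param dir corpus directory
#' @return list of manifest entries (one per recording)
#' @export
read_manifest <- function(dir) {
  path <- manifest_path(dir)
  if (!file.exists(path)) stop("missing manifest: ", path)
  lapply(readLines(path), jsonlite::fromJSON, simplifyDataFrame = TRUE)
}

#' Write an annotated recording as WFDB files plus a manifest line
#'
#' @param rec an [annotated_recording()]
#' @param dir destination directory (created if needed)
#' @return paths of the written files, invisibly
#' @export
write_annotated_recording <- function(rec, dir) {
  validate_recording(rec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  record <- paste0(rec$patient_id, "_", rec$segment_id)
  p1 <- write_wfdb_signal(rec$signal, rec$fs, record, dir)
  p2 <- write_wfdb_annotations(rec$beats, record, dir)
  append_manifest(dir, list(record = record, patient_id = rec$patient_id,
                            segment_id = rec$segment_id, fs = rec$fs,
                            n_samples = length(rec$signal),
                            rhythms = rec$rhythms))
  invisible(c(p1, p2))
}

#' Read an annotated recording written by [write_annotated_recording()]
#'
#' @param path_base record path without extension (e.g. `dir/p00000_s00`)
#' @return an [annotated_recording()]; invariants are validated on load
#' @export
read_annotated_recording <- function(path_base) {
  sig <- read_wfdb_signal(path_base)
  beats <- read_wfdb_annotations(path_base)
  if (nrow(beats) > 0 && any(beats$sample >= sig$n))
    stop("annotation index beyond signal length in ", path_base, ".atr")
  dir <- dirname(path_base)
  record <- basename(path_base)
  entries <- read_manifest(dir)
  hit <- Filter(function(e) identical(e$record, record), entries)
  if (length(hit) == 0) stop("record ", record, " not found in ", manifest_path(dir))
  e <- hit[[1]]
  rhythms <- as.data.frame(e$rhythms, stringsAsFactors = FALSE)
  annotated_recording(sig$signal, sig$fs, beats, rhythms,
                      patient_id = e$patient_id, segment_id = e$segment_id)
}
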