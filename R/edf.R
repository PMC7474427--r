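# Minimal reader for continuous EDF recordings (base-R binary parsing).

#' Read a continuous EEG recording from an EDF file
#'
#' Parses the European Data Format header and data records (16-bit little-
#' endian samples, rescaled to physical units) and returns the requested
#' channels as a [continuous_recording()]. All selected channels must share
#' one sampling rate. EDF+ annotation channels are ignored; event markers
#' must be supplied separately (the `events` argument), since trigger
#' encodings vary across acquisition systems.
#'
#' @param path EDF file path.
#' @param channels channel labels to keep (default C3, Cz, C4; matching is
#'   case-insensitive on the trimmed label, so "EEG C3" matches "C3").
#' @param events optional data frame with columns `sample`, `label`.
#' @return a [continuous_recording()].
#' @export
read_edf <- function(path, channels = c("C3", "Cz", "C4"),
                     events = data.frame(sample = integer(), label = character())) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  rd_str(8)                       # version
  rd_str(80); rd_str(80)          # patient / recording id
  rd_str(8); rd_str(8)            # start date / time
  rd_str(8)                       # header bytes
  rd_str(44)                      # reserved
  n_rec <- as.integer(rd_str(8))
  rec_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  labels <- vapply(seq_len(ns), function(i) rd_str(16), "")
  for (i in seq_len(ns)) rd_str(80)   # transducer
  for (i in seq_len(ns)) rd_str(8)    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  for (i in seq_len(ns)) rd_str(80)   # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd_str(8)), 0L)
  for (i in seq_len(ns)) rd_str(32)   # reserved
  clean <- toupper(trimws(sub("^EEG[ :]*", "", toupper(labels))))
  want <- match(toupper(channels), clean)
  if (anyNA(want))
    stop("channels not found in EDF: ",
         paste(channels[is.na(want)], collapse = ", "))
  if (length(unique(nsamp[want])) != 1)
    stop("selected channels have differing sampling rates")
  fs <- nsamp[want[1]] / rec_dur
  gain <- (phys_max - phys_min) / pmax(dig_max - dig_min, 1)
  sig <- matrix(0, length(want), n_rec * nsamp[want[1]])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2,
                     signed = TRUE, endian = "little")
      ki <- match(i, want)
      if (!is.na(ki)) {
        idx <- ((r - 1) * nsamp[i] + 1):(r * nsamp[i])
        sig[ki, idx] <- phys_min[i] + gain[i] * (raw - dig_min[i])
      }
    }
  }
  continuous_recording(sig, fs, events, channels)
}
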