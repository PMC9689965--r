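# Minimal EDF/EDF+ I/O, sufficient for the PhysioNet motor imagery dialect:
# 16-bit little-endian samples, one continuous segment ("EDF+C"), one
# "EDF Annotations" signal carrying time-stamped annotation lists (TALs).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(v, width = 8) {
  s <- format(v, trim = TRUE, scientific = FALSE)
  if (nchar(s) > width) s <- formatC(v, digits = width - 6, format = "e")
  if (nchar(s) > width) stop("cannot format ", v, " in ", width, " chars")
  edf_pad(s, width)
}

#' Write a recording to an EDF+ file
#'
#' Writes 16-bit EDF+C with one-second data records, a symmetric physical
#' range per channel, and an `EDF Annotations` signal holding the recording's
#' event annotations.  Intended for round-trip tests and interoperability;
#' amplitudes are quantized to the 16-bit grid.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(is_recording(rec))
  fs <- rec$sample_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sample rate")
  n_ch <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  n_rec <- ceiling(n_samp / fs)
  # symmetric physical range; digital range -32768..32767
  amax <- max(abs(rec$data), 1e-6)
  amax <- as.numeric(formatC(amax * 1.0001, digits = 5, format = "g"))
  anno_len <- 80L  # samples (2 bytes each) reserved per record for TALs

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width, eos = NULL)
  ns <- n_ch + 1L
  wr("0", 8); wr(rec$subject_id, 80)
  wr(paste("Startdate 01-JAN-2000", rec$run_id, rec$state), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8); wr("EDF+C", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  labs <- c(rec$channel_labels, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)                      # transducer
  for (i in seq_len(ns)) wr(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(edf_num(if (i <= n_ch) -amax else -1), 8)
  for (i in seq_len(ns)) wr(edf_num(if (i <= n_ch) amax else 1), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)                      # prefiltering
  for (i in seq_len(ns)) wr(if (i <= n_ch) fs else anno_len, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- 65535 / (2 * amax)
  dig <- matrix(0L, nrow = n_ch, ncol = n_rec * fs)
  dig[, seq_len(n_samp)] <- as.integer(round(pmin(pmax(rec$data, -amax), amax) * scale))
  ann <- rec$annotations
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2, endian = "little")
    # TALs for this record: timestamp first, then events starting in it
    tal <- sprintf("+%d\x14\x14", r - 1L)
    if (nrow(ann)) {
      here <- ann[ann$onset >= idx[1] & ann$onset <= idx[fs], , drop = FALSE]
      for (j in seq_len(nrow(here)))
        tal <- paste0(tal, sprintf("+%.7g\x15%.7g\x14%s\x14",
                                   (here$onset[j] - 1) / fs,
                                   here$duration[j] / fs, here$label[j]))
    }
    raw_tal <- c(charToRaw(tal), raw(2L * anno_len - length(charToRaw(tal))))
    if (length(raw_tal) != 2L * anno_len)
      stop("annotation block overflow in record ", r)
    writeBin(raw_tal, con)
  }
  invisible(path)
}

# PhysioNet eegmmidb run-number conventions.
run_task_type <- function(run_id) {
  n <- suppressWarnings(as.integer(sub(".*R(\\d+).*", "\\1", run_id)))
  if (is.na(n)) return("unknown")
  if (n == 1) "eyes_open"
  else if (n == 2) "eyes_closed"
  else if (n %in% c(4, 8, 12)) "left_right"
  else if (n %in% c(6, 10, 14)) "hands_feet"
  else "other"
}

#' Read an EDF/EDF+ file into an [eeg_recording()]
#'
#' Reads 16-bit EDF, normalizes channel labels (PhysioNet's trailing-dot
#' names like `"C3.."` become canonical `"C3"`), reorders channels to the
#' canonical montage, standardizes units to microvolts, and decodes EDF+
#' annotations into sample-indexed event labels.  For motor-imagery runs the
#' generic `T1`/`T2` event codes are mapped to task labels according to the
#' run type (left/right-hand runs vs. both-hands/feet runs), inferred from
#' the file name (`R04`, `R08`, ... per the PhysioNet numbering) unless given.
#'
#' @param path EDF file path.
#' @param task Run type used to decode `T1`/`T2` annotations: `"auto"`
#'   (default, from the file name), `"left_right"`, `"hands_feet"` or
#'   `"none"` (keep raw codes).
#' @param require_montage If `TRUE` (default), error unless all 64 canonical
#'   channels are present; the error names the missing labels.
#' @param exclude Optional character vector of subject ids to reject (the
#'   source database contains a few subjects with unusable labels; the list
#'   is user-supplied, not hard-coded).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, task = c("auto", "left_right", "hands_feet", "none"),
                     require_montage = TRUE, exclude = character()) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (nchar(s, type = "bytes") < width) stop("malformed EDF: truncated header")
    trimws(s)
  }
  rd(8)                                   # version
  patient <- rd(80); rec_field <- rd(80)
  rd(8); rd(8)                            # date, time
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF: bad 'number of signals' field")
  if (is.na(n_rec) || n_rec < 0) stop("malformed EDF: bad 'number of records' field")
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_)))
    stop("malformed EDF: non-numeric physical/digital min/max field")
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (is.na(header_bytes) || header_bytes != 256L * (ns + 1L))
    stop("malformed EDF: 'number of bytes in header' field inconsistent")

  is_anno <- labs == "EDF Annotations"
  if (!any(is_anno))
    stop("EDF file has no annotation track ('EDF Annotations' signal missing)")
  sig_idx <- which(!is_anno)
  raw_sig <- vector("list", ns)
  for (i in seq_len(ns)) raw_sig[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < spr[i]) stop("malformed EDF: truncated data record ", r)
      raw_sig[[i]][[r]] <- v
    }
  }

  fs <- spr[sig_idx[1]] / rec_dur
  rows <- lapply(sig_idx, function(i) {
    v <- unlist(raw_sig[[i]], use.names = FALSE)
    g <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    phys <- pmin_[i] + g * (v - dmin_[i])
    u <- tolower(dims[i])
    if (u == "mv") phys <- phys * 1e3 else if (u == "v") phys <- phys * 1e6
    phys
  })
  data <- do.call(rbind, rows)
  chan <- normalize_channel_label(labs[sig_idx])

  # annotations: concatenate all TAL bytes and split
  ann_raw <- unlist(lapply(which(is_anno), function(i)
    lapply(raw_sig[[i]], function(v) {
      b <- writeBin(as.integer(v), raw(), size = 2, endian = "little")
      b
    })), use.names = FALSE)
  txt <- rawToChar(as.raw(ann_raw[ann_raw != as.raw(0)]))
  onset <- numeric(); dur <- numeric(); lab <- character()
  for (t in strsplit(txt, "(?<=\x14)(?=\\+)", perl = TRUE)[[1]]) {
    parts <- strsplit(t, "\x14")[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next  # timekeeping TAL
    od <- strsplit(parts[1], "\x15")[[1]]
    onset <- c(onset, as.numeric(od[1]))
    dur <- c(dur, if (length(od) > 1) as.numeric(od[2]) else 0)
    lab <- c(lab, parts[2])
  }

  run_id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  subject_id <- sub("^(S\\d+).*", "\\1", run_id)
  if (subject_id %in% exclude)
    stop("subject ", subject_id, " is on the exclusion list")
  ttype <- if (task == "auto") run_task_type(run_id) else task
  state <- switch(ttype, eyes_open = "eyes_open", eyes_closed = "eyes_closed",
                  "mi_run")
  map <- switch(ttype,
    left_right = c(T0 = "rest", T1 = "left_hand", T2 = "right_hand"),
    hands_feet = c(T0 = "rest", T1 = "both_hands", T2 = "feet"),
    NULL)
  if (!is.null(map) && length(lab)) {
    known <- lab %in% names(map)
    lab[known] <- map[lab[known]]
  }
  ann <- data.frame(onset = as.integer(round(onset * fs)) + 1L,
                    duration = as.integer(round(dur * fs)),
                    label = lab, stringsAsFactors = FALSE)

  if (require_montage) {
    missing <- setdiff(eegmmidb_channels(), chan)
    if (length(missing))
      stop("EDF file lacks canonical montage channels: ",
           paste(missing, collapse = ", "))
  }
  rec <- eeg_recording(data, fs, chan, subject_id = subject_id,
                       run_id = run_id, state = state, annotations = ann)
  align_to_montage(rec)
}
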