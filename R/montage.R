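#' The 21-channel mental-arithmetic montage
#'
#' The channel labels of the public mental-arithmetic recordings: 20 EEG
#' channels of the 10-20 system plus one ECG channel. Region counts are
#' frontal 7 (6 + Fz), temporal 4, central 3 (2 + Cz), parietal 3
#' (2 + Pz), occipital 2, behind-ear 1, ECG 1.
#'
#' @return character(21) channel labels.
#' @seealso [channelGroup()]
#' @export
eegmatMontage <- function() {
  c("EEG Fp1", "EEG Fp2", "EEG F3", "EEG F4", "EEG F7", "EEG F8", "EEG Fz",
    "EEG T3", "EEG T4", "EEG T5", "EEG T6",
    "EEG C3", "EEG C4", "EEG Cz",
    "EEG P3", "EEG P4", "EEG Pz",
    "EEG O1", "EEG O2",
    "EEG A2-A1",
    "ECG ECG")
}

.group_names <- c("frontal", "temporal", "central", "parietal",
                  "occipital", "behind_ear", "ecg", "all")

.channel_region <- function(label) {
  if (grepl("ECG", label, fixed = TRUE)) return("ecg")
  nm <- sub("^EEG +", "", label)
  first <- toupper(substr(nm, 1, 1))
  switch(first,
    F = "frontal",   # covers Fp* and F*
    T = "temporal",
    C = "central",
    P = "parietal",
    O = "occipital",
    A = "behind_ear",
    M = "behind_ear",
    NA_character_)
}

#' Map channels to an anatomical group
#'
#' Deterministic grouping by 10-20 label prefix after stripping an
#' optional `"EEG "` prefix: `Fp*`/`F*` frontal, `T*` temporal, `C*`
#' central, `P*` parietal, `O*` occipital, `A*`/`M*` behind-ear, any
#' label containing `ECG` the ECG group; `"all"` returns the whole
#' montage. For the standard montage the seven non-`all` groups
#' partition the channel set.
#'
#' @param montage character vector of channel labels.
#' @param name one of `"frontal"`, `"temporal"`, `"central"`,
#'   `"parietal"`, `"occipital"`, `"behind_ear"`, `"ecg"`, `"all"`.
#' @param overrides optional named list of character vectors replacing
#'   the prefix rule for specific groups (e.g. read from a YAML config
#'   with keys `groups.<name>`); members must belong to the montage.
#' @return character vector, the group's member channels (order of the
#'   montage).
#' @examples
#' channelGroup(eegmatMontage(), "frontal")
#' channelGroup(eegmatMontage(), "ecg")
#' @export
channelGroup <- function(montage, name, overrides = NULL) {
  if (!is.character(name) || length(name) != 1L || !name %in% .group_names)
    stop("unknown channel group '", paste(name, collapse = ","),
         "'; expected one of: ", paste(.group_names, collapse = ", "))
  if (!is.null(overrides) && !is.null(overrides[[name]])) {
    members <- as.character(overrides[[name]])
    bad <- setdiff(members, montage)
    if (length(bad))
      stop("group override for '", name, "' names channels not in the montage: ",
           paste(bad, collapse = ", "))
    return(montage[montage %in% members])
  }
  if (name == "all") return(montage)
  regions <- vapply(montage, .channel_region, "")
  montage[!is.na(regions) & regions == name]
}

#' Read channel-group overrides from a YAML config
#'
#' Expects a top-level `groups` mapping whose keys are group names and
#' values are lists of channel labels.
#'
#' @param path YAML file path.
#' @return named list suitable for `channelGroup(overrides = )`.
#' @export
readGroupOverrides <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read group overrides")
  cfg <- yaml::read_yaml(path)
  g <- cfg$groups
  if (is.null(g)) stop("config '", path, "' has no 'groups' key")
  lapply(g, as.character)
}

#' Read the subject-label table
#'
#' Parses the performance/quality table accompanying the recordings
#' (CSV or TSV). The subject column is recognised under the names
#' `subject_id`, `subject` or `id`; the quality column under `quality`,
#' `count_quality`, `count quality` or `label` (all case-insensitive).
#' Quality tokens are normalised to `"G"` (good / non-stressed) or
#' `"B"` (bad / stressed): accepted spellings are G/B, good/bad and the
#' numeric coding 1/0 used by the public table.
#'
#' @param path delimited text file; the delimiter (comma or tab) is
#'   sniffed from the header line.
#' @return data.frame with columns `subject_id`, `quality`, plus
#'   `n_subtractions`, `age` and `gender` when present in the input.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,quality", "s1,G", "s2,g", "s3,0"), f)
#' readLabels(f)
#' @export
readLabels <- function(path) {
  if (!file.exists(path))
    stop("cannot read label file '", path, "': no such file")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  norm <- function(x) gsub("[ _.]", "", tolower(x))
  cn <- norm(names(df))
  pick <- function(cands) {
    i <- which(cn %in% cands)
    if (length(i)) i[1] else NA_integer_
  }
  si <- pick(c("subjectid", "subject", "id", "name"))
  qi <- pick(c("quality", "countquality", "label"))
  if (nrow(df) == 0L) {
    return(data.frame(subject_id = character(), quality = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.na(si))
    stop("label file '", path, "' has no recognisable subject column")
  if (is.na(qi))
    stop("label file '", path, "' has no recognisable quality column")
  qraw <- trimws(as.character(df[[qi]]))
  qmap <- c(g = "G", good = "G", "1" = "G", b = "B", bad = "B", "0" = "B")
  q <- qmap[tolower(qraw)]
  if (anyNA(q)) {
    bad <- unique(qraw[is.na(q)])
    stop("unknown quality token(s) in '", path, "': ",
         paste(bad, collapse = ", "), " (expected G/B, good/bad or 1/0)")
  }
  out <- data.frame(subject_id = as.character(df[[si]]), quality = unname(q),
                    stringsAsFactors = FALSE)
  ni <- pick(c("nsubtractions", "numberofsubtractions", "subtractions"))
  if (!is.na(ni)) out$n_subtractions <- as.numeric(df[[ni]])
  ai <- pick(c("age"))
  if (!is.na(ai)) out$age <- as.numeric(df[[ai]])
  gi <- pick(c("gender", "sex"))
  if (!is.na(gi)) out$gender <- toupper(substr(trimws(as.character(df[[gi]])), 1, 1))
  out
}
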