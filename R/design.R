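#' Stimulus-onset-asynchrony levels of the Ternus designs
#'
#' The seven interstimulus intervals (ISI, frame offset to next frame onset)
#' are 50--230 ms in 30-ms steps; each Ternus frame lasts 30 ms, so
#' SOA = ISI + 30 ms, giving SOAs 80--260 ms.
#'
#' @return Integer vector of the seven SOA levels in ms.
#' @export
soa_levels <- function() isi_levels() + frame_duration_ms()

#' @rdname soa_levels
#' @export
isi_levels <- function() c(50L, 80L, 110L, 140L, 170L, 200L, 230L)

#' @rdname soa_levels
#' @export
frame_duration_ms <- function() 30L

#' Build one of the four Ternus experiment designs
#'
#' Constructs the per-trial design table for a single session of one of the
#' four experiments:
#' \describe{
#'   \item{E1}{Fully randomized: 24 trials per SOA x sound cell
#'     (7 SOAs x 2 sound conditions x 24 = 336 trials), left/right apparent
#'     motion balanced 12/12 within each cell, presented in 2 blocks of 168.}
#'   \item{E2}{Sound blocked: 4 blocks of 84 trials, 2 all-sound and 2
#'     no-sound blocks in seeded counterbalanced order; within a block 12
#'     trials per SOA, 6 leftward/6 rightward.}
#'   \item{E3}{SOA blocked: one block per SOA level in seeded order; within a
#'     block sound and direction are counterbalanced.}
#'   \item{E4}{Control (visual localization): identical structure and timeline
#'     to E1 but the Ternus frames are not displayed (`has_frames = FALSE`);
#'     the nominal frame times are retained as timeline reference points.}
#' }
#'
#' Each trial carries a timeline (ms from trial start): a pre-trial central
#' fixation of uniformly 3--5 s, then peripheral fixation (200 ms), blank
#' (100 ms), central fixation (200 ms) and blank (300 ms) before the first
#' Ternus frame; frames last 30 ms; beep onsets coincide with frame onsets on
#' sound trials; the response probe appears 300 ms after the second frame's
#' offset.
#'
#' @param experiment_id One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param seed Integer seed; trial order (and fixation durations) are a pure
#'   function of `(experiment_id, seed)`.
#' @param e3_block_trials Trials per fixed-SOA block in E3: 24 (default,
#'   total 168) or 168 (total 1176).
#' @return An object of class `ternus_design`: a list with `experiment_id`,
#'   `trials` (data.frame, one row per trial in presented order), `blocks`
#'   (data.frame of block index and constraint label) and `seed`.
#' @export
build_design <- function(experiment_id = c("E1", "E2", "E3", "E4"), seed = 1L,
                         e3_block_trials = 24L) {
  experiment_id <- match.arg(experiment_id)
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  soas <- soa_levels()

  if (experiment_id %in% c("E1", "E4")) {
    cells <- expand.grid(soa_ms = soas, sound = c(FALSE, TRUE),
                         direction = c("left", "right"),
                         rep = seq_len(12L), stringsAsFactors = FALSE)
    cells <- cells[sample.int(nrow(cells)), ]
    cells$block <- rep(1:2, each = 168L)
    blocks <- data.frame(block = 1:2, label = "mixed",
                         stringsAsFactors = FALSE)
  } else if (experiment_id == "E2") {
    block_sound <- sample(c(TRUE, TRUE, FALSE, FALSE))
    cells <- do.call(rbind, lapply(1:4, function(b) {
      d <- expand.grid(soa_ms = soas, direction = c("left", "right"),
                       rep = seq_len(6L), stringsAsFactors = FALSE)
      d <- d[sample.int(nrow(d)), ]
      d$sound <- block_sound[b]
      d$block <- b
      d
    }))
    blocks <- data.frame(block = 1:4,
                         label = ifelse(block_sound, "sound", "no-sound"),
                         stringsAsFactors = FALSE)
  } else { # E3
    if (!e3_block_trials %in% c(24L, 168L))
      stop("e3_block_trials must be 24 or 168")
    n_rep <- e3_block_trials / 4L # sound x direction counterbalanced
    block_soa <- sample(soas)
    cells <- do.call(rbind, lapply(seq_along(block_soa), function(b) {
      d <- expand.grid(sound = c(FALSE, TRUE),
                       direction = c("left", "right"),
                       rep = seq_len(n_rep), stringsAsFactors = FALSE)
      d <- d[sample.int(nrow(d)), ]
      d$soa_ms <- block_soa[b]
      d$block <- b
      d
    }))
    blocks <- data.frame(block = seq_along(block_soa),
                         label = paste0("soa_", block_soa),
                         stringsAsFactors = FALSE)
  }

  n <- nrow(cells)
  fd <- frame_duration_ms()
  # pre-trial fixation 3-5 s, rounded onto the 2-ms sample grid
  fix_dur <- round(stats::runif(n, 3000, 5000) / 2) * 2
  frame1 <- fix_dur + 200 + 100 + 200 + 300
  trials <- data.frame(
    trial_id = seq_len(n),
    block = cells$block,
    soa_ms = cells$soa_ms,
    isi_ms = cells$soa_ms - fd,
    sound = cells$sound,
    direction = cells$direction,
    has_frames = experiment_id != "E4",
    fix_dur_ms = fix_dur,
    frame1_ms = frame1,
    frame2_ms = frame1 + cells$soa_ms,
    probe_ms = frame1 + cells$soa_ms + fd + 300,
    stringsAsFactors = FALSE
  )
  trials$beep1_ms <- ifelse(trials$sound, trials$frame1_ms, NA_real_)
  trials$beep2_ms <- ifelse(trials$sound, trials$frame2_ms, NA_real_)
  rownames(trials) <- NULL

  structure(list(experiment_id = experiment_id, trials = trials,
                 blocks = blocks, seed = as.integer(seed)),
            class = "ternus_design")
}

#' @export
print.ternus_design <- function(x, ...) {
  cat(sprintf("<ternus_design %s: %d trials, %d blocks, seed %d>\n",
              x$experiment_id, nrow(x$trials), nrow(x$blocks), x$seed))
  invisible(x)
}

#' Check the structural invariants of a design
#'
#' Verifies trial counts per cell, left/right balance, the SOA = ISI + 30 ms
#' relation, block homogeneity (E2/E3) and timeline consistency. Used by the
#' generator and by the test suite.
#'
#' @param design A `ternus_design`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "ternus_design"))
  tr <- design$trials
  if (!all(tr$soa_ms - tr$isi_ms == frame_duration_ms()))
    stop("SOA != ISI + frame duration")
  if (!all(tr$soa_ms %in% soa_levels()))
    stop("SOA outside the design set")
  if (any(tr$fix_dur_ms < 3000 | tr$fix_dur_ms > 5000))
    stop("pre-trial fixation outside 3-5 s")
  if (!all(tr$frame2_ms - tr$frame1_ms == tr$soa_ms))
    stop("frame2 onset != frame1 onset + SOA")
  if (!all(tr$probe_ms - tr$frame2_ms == frame_duration_ms() + 300))
    stop("probe onset != frame2 offset + 300 ms")
  if (any(tr$sound & (tr$beep1_ms != tr$frame1_ms | tr$beep2_ms != tr$frame2_ms),
          na.rm = TRUE))
    stop("beep onsets do not coincide with frame onsets")

  id <- design$experiment_id
  if (id %in% c("E1", "E4")) {
    if (nrow(tr) != 336L) stop("E1/E4 must have 336 trials")
    counts <- table(tr$soa_ms, tr$sound)
    if (!all(counts == 24L)) stop("E1/E4: not 24 trials per SOA x sound cell")
    bal <- table(tr$soa_ms, tr$sound, tr$direction)
    if (!all(bal == 12L)) stop("E1/E4: direction not balanced 12/12 per cell")
    if (id == "E4" && any(tr$has_frames)) stop("E4 trials must not carry frames")
  } else if (id == "E2") {
    if (nrow(tr) != 336L) stop("E2 must have 336 trials")
    per_block <- table(tr$block)
    if (!all(per_block == 84L)) stop("E2: blocks must contain 84 trials")
    hom <- tapply(tr$sound, tr$block, function(s) length(unique(s)) == 1L)
    if (!all(hom)) stop("E2: blocks must be homogeneous in sound condition")
    sb <- tapply(tr$sound, tr$block, unique)
    if (sum(unlist(sb)) != 2L) stop("E2: need 2 sound and 2 no-sound blocks")
    within <- table(tr$block, tr$soa_ms)
    if (!all(within == 12L)) stop("E2: not 12 trials per SOA within block")
    dirw <- table(tr$block, tr$soa_ms, tr$direction)
    if (!all(dirw == 6L)) stop("E2: direction not balanced 6/6 within block")
  } else { # E3
    soa_per_block <- tapply(tr$soa_ms, tr$block, function(s) length(unique(s)))
    if (!all(soa_per_block == 1L)) stop("E3: blocks must have a fixed SOA")
    if (length(unique(tr$block)) != 7L) stop("E3: need one block per SOA level")
    cnt <- table(tr$block, tr$sound, tr$direction)
    if (length(unique(as.vector(cnt))) != 1L)
      stop("E3: sound x direction not counterbalanced within block")
  }
  invisible(TRUE)
}
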