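# Head/tail identity assignment and propagation across frames.

# Orient a posture so that skeleton and ends run head -> tail, given which
# candidate row of p$ends is the head.
orient_posture <- function(p, head_idx) {
  head <- p$ends[head_idx, ]
  tail <- p$ends[3L - head_idx, ]
  p$head <- c(x = unname(head[1]), y = unname(head[2]))
  p$tail <- c(x = unname(tail[1]), y = unname(tail[2]))
  if (!is.null(p$skeleton)) {
    d_first <- pt_dist(head, p$skeleton[1, ])
    d_last <- pt_dist(head, p$skeleton[nrow(p$skeleton), ])
    if (d_last < d_first)
      p$skeleton <- p$skeleton[nrow(p$skeleton):1, , drop = FALSE]
  }
  p
}

#' Seed head/tail identity in the first frame
#'
#' Assigns the candidate endpoint nearest `head_hint` as the head and the
#' other as the tail. The hints replace the interactive clicks near the
#' head and tail used to initialize identity in the first frame.
#'
#' @param posture A `posture` object with two candidate ends.
#' @param head_hint,tail_hint (x, y) points near the head and tail.
#' @return The posture with `head`/`tail` set and skeleton ordered
#'   head to tail.
#' @export
seed_identity <- function(posture, head_hint, tail_hint) {
  ends <- posture$ends
  dh <- c(pt_dist(ends[1, ], head_hint), pt_dist(ends[2, ], head_hint))
  dt <- c(pt_dist(ends[1, ], tail_hint), pt_dist(ends[2, ], tail_hint))
  if (which.min(dh) == which.min(dt)) stopf("ambiguous_seed")
  orient_posture(posture, which.min(dh))
}

#' Propagate head identity from the previous frame
#'
#' The distance rule: the head in the current frame is the candidate
#' closest to the head in the previous frame. The rule uses position only,
#' so it works for stationary and backward-moving animals; it requires
#' the per-frame head displacement to be small relative to the body
#' length (tracking faster than the motion speed in body-length units).
#' Candidates equidistant within `tie_tol` are resolved by body-axis
#' direction continuity and flagged `swap_suspect`.
#'
#' @param prev Labeled `posture` of the previous frame.
#' @param curr Unlabeled `posture` of the current frame.
#' @param tie_tol Tie tolerance in px.
#' @return Labeled current posture.
#' @export
propagate_identity <- function(prev, curr, tie_tol = 1) {
  ends <- curr$ends
  d <- c(pt_dist(ends[1, ], prev$head), pt_dist(ends[2, ], prev$head))
  if (abs(d[1] - d[2]) <= tie_tol) {
    prev_axis <- prev$head - prev$tail
    ax1 <- ends[1, ] - ends[2, ]
    pick <- if (sum(prev_axis * ax1) >= 0) 1L else 2L
    curr <- orient_posture(curr, pick)
    curr$flags <- union(curr$flags, "swap_suspect")
  } else {
    curr <- orient_posture(curr, which.min(d))
  }
  curr
}

#' Label a whole trajectory
#'
#' Seeds identity in the first frame and propagates it through all frames,
#' then flags ambiguous frames.
#'
#' @param postures List of `posture` objects, time ordered.
#' @param head_hint,tail_hint Seed points for the first frame.
#' @param tie_tol Tie tolerance passed to [propagate_identity()].
#' @return A `labeled_trajectory`: `list(postures, flagged_frames,
#'   corrections)`.
#' @export
label_trajectory <- function(postures, head_hint, tail_hint, tie_tol = 1) {
  postures[[1]] <- seed_identity(postures[[1]], head_hint, tail_hint)
  for (i in seq_along(postures)[-1]) {
    postures[[i]] <- propagate_identity(postures[[i - 1]], postures[[i]],
                                        tie_tol)
  }
  structure(list(postures = postures,
                 flagged_frames = flag_ambiguities(postures),
                 corrections = NULL),
            class = "labeled_trajectory")
}

#' Flag frames with suspect head/tail assignment
#'
#' Flags (a) blob-like postures (strong bending can swap head and tail),
#' (b) frames whose head moved more than half a skeleton length since the
#' previous frame, and (c) frames where the distance rule tied.
#'
#' @param trajectory A `labeled_trajectory` or list of labeled postures.
#' @param max_jump Head displacement threshold as a fraction of skeleton
#'   length.
#' @return data.frame with columns `frame` (1-based) and `reason`.
#' @export
flag_ambiguities <- function(trajectory, max_jump = 0.5) {
  postures <- if (inherits(trajectory, "labeled_trajectory"))
    trajectory$postures else trajectory
  out <- list()
  add <- function(frame, reason)
    out[[length(out) + 1L]] <<- data.frame(frame = frame, reason = reason)
  for (i in seq_along(postures)) {
    p <- postures[[i]]
    if ("blob_like" %in% p$flags) add(i, "blob_like")
    if ("swap_suspect" %in% p$flags) add(i, "tie")
    if (i > 1L) {
      jump <- pt_dist(p$head, postures[[i - 1]]$head)
      if (jump > max_jump * p$skeleton_length) add(i, "head_jump")
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), reason = character(0)))
  do.call(rbind, out)
}

#' Apply review corrections to a labeled trajectory
#'
#' Replays a corrections table (the versionable replacement for the
#' interactive review animation): `swap` exchanges head and tail from that
#' frame onward until the next correction, `discard` marks the single
#' frame discarded, `keep` clears its flags.
#'
#' @param trajectory A `labeled_trajectory`.
#' @param corrections data.frame with columns `frame`, `action`
#'   (one of `"swap"`, `"discard"`, `"keep"`).
#' @return The corrected `labeled_trajectory`; remaining (uncorrected)
#'   flags are in `$flagged_frames`.
#' @export
resolve_flags <- function(trajectory, corrections) {
  stopifnot(inherits(trajectory, "labeled_trajectory"))
  postures <- trajectory$postures
  if (is.null(corrections) || !nrow(corrections)) {
    trajectory$corrections <- corrections
    return(trajectory)
  }
  corrections <- corrections[order(corrections$frame), , drop = FALSE]
  flagged <- trajectory$flagged_frames$frame
  bounds <- c(corrections$frame, length(postures) + 1L)
  for (k in seq_len(nrow(corrections))) {
    fr <- corrections$frame[k]
    action <- corrections$action[k]
    if (!(fr %in% flagged))
      warning(sprintf("correction on unflagged frame %d", fr))
    if (action == "swap") {
      for (i in fr:(bounds[k + 1L] - 1L)) {
        p <- postures[[i]]
        head_idx <- which.min(c(pt_dist(p$ends[1, ], p$tail),
                                pt_dist(p$ends[2, ], p$tail)))
        postures[[i]] <- orient_posture(p, head_idx)
      }
    } else if (action == "discard") {
      postures[[fr]]$flags <- union(postures[[fr]]$flags, "discarded")
    }
  }
  handled <- corrections$frame
  remaining <- trajectory$flagged_frames[
    !(trajectory$flagged_frames$frame %in% handled), , drop = FALSE]
  structure(list(postures = postures, flagged_frames = remaining,
                 corrections = corrections),
            class = "labeled_trajectory")
}
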