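#include <Rcpp.h>
using namespace Rcpp;

// Per-read mean Phred score from a Phred+33 quality string.
// [[Rcpp::export]]
NumericVector cpp_mean_qual(CharacterVector qual) {
  int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = LENGTH(STRING_ELT(qual, i));
    if (len == 0) { out[i] = NA_REAL; continue; }
    long s = 0;
    for (int j = 0; j < len; ++j) s += q[j] - 33;
    out[i] = (double)s / len;
  }
  return out;
}

// Overlap-merge one read pair per element. `fwd` is the forward read,
// `revrc` the reverse-complemented reverse read (so both are in insert
// orientation); `rq` is the reverse mate's quality string, still in read
// order (index k of revrc corresponds to quality position len-1-k).
// Candidate insert sizes run from min_n to max_n; the size minimizing
// overlap disagreements wins (ties go to the larger overlap). At retained
// disagreeing positions the higher-quality base is used.
// status: 0 = merged, 1 = mates_disagree (no candidate within tolerance).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector revrc,
                     CharacterVector fq, CharacterVector rq,
                     int min_n, int max_n, int min_overlap,
                     int max_disagreements) {
  int n = fwd.size();
  CharacterVector merged(n), mqual(n);
  IntegerVector status(n), ins_len(n);
  std::string buf, qbuf;
  for (int i = 0; i < n; ++i) {
    const char *f = CHAR(STRING_ELT(fwd, i));
    const char *r = CHAR(STRING_ELT(revrc, i));
    const char *qf = CHAR(STRING_ELT(fq, i));
    const char *qr = CHAR(STRING_ELT(rq, i));
    int lf = LENGTH(STRING_ELT(fwd, i));
    int lr = LENGTH(STRING_ELT(revrc, i));
    int lo = std::max(std::max(lf, lr), min_n);
    int best_n = -1, best_mm = INT_MAX;
    for (int N = lo; N <= max_n; ++N) {
      int o = lf + lr - N;            // overlap length
      if (o < min_overlap) break;     // shrinks as N grows
      int start = N - lr;             // first overlapped insert position
      int mm = 0;
      for (int j = 0; j < o; ++j)
        if (f[start + j] != r[j]) ++mm;
      if (mm < best_mm) { best_mm = mm; best_n = N; }
      if (mm == 0) break;             // cannot do better; prefers larger overlap
    }
    if (best_n < 0 || best_mm > max_disagreements) {
      status[i] = 1;
      merged[i] = NA_STRING; mqual[i] = NA_STRING; ins_len[i] = NA_INTEGER;
      continue;
    }
    int N = best_n, start = N - lr;
    buf.assign(N, 'N'); qbuf.assign(N, '!');
    for (int p = 0; p < N; ++p) {
      bool in_f = p < lf, in_r = p >= start;
      char qa = in_f ? qf[p] : '!';
      // reverse mate quality is in read order: revrc index k <-> rq[lr-1-k]
      char qb = in_r ? qr[lr - 1 - (p - start)] : '!';
      if (in_f && in_r) {
        if (f[p] == r[p - start]) {
          buf[p] = f[p]; qbuf[p] = qa > qb ? qa : qb;
        } else if (qa >= qb) {
          buf[p] = f[p]; qbuf[p] = qa;
        } else {
          buf[p] = r[p - start]; qbuf[p] = qb;
        }
      } else if (in_f) {
        buf[p] = f[p]; qbuf[p] = qa;
      } else {
        buf[p] = r[p - start]; qbuf[p] = qb;
      }
    }
    status[i] = 0;
    merged[i] = buf; mqual[i] = qbuf; ins_len[i] = N;
  }
  return List::create(_["status"] = status, _["merged"] = merged,
                      _["qual"] = mqual, _["insert_len"] = ins_len);
}

static inline int hamming_at(const char *s, int slen, const char *pat,
                             int plen, int off) {
  if (off < 0 || off + plen > slen) return INT_MAX;
  int mm = 0;
  for (int j = 0; j < plen; ++j)
    if (s[off + j] != pat[j]) ++mm;
  return mm;
}

static int best_offset(const char *s, int slen, const char *pat, int plen,
                       int expected, int window, int *mm_out) {
  int best = -1, best_mm = INT_MAX;
  for (int d = 0; d <= window; ++d) {
    // expand outward so ties resolve to the expected offset
    for (int sgn = 0; sgn < 2; ++sgn) {
      if (d == 0 && sgn == 1) continue;
      int off = expected + (sgn == 0 ? d : -d);
      int mm = hamming_at(s, slen, pat, plen, off);
      if (mm < best_mm) { best_mm = mm; best = off; }
    }
  }
  *mm_out = best_mm;
  return best;
}

// Anchor the fixed regions of a merged insert (substitution-only matching,
// each region searched within +/- window of its architectural offset) and
// cut out the template and product windows. Sequences are DNA-alphabet here.
// status: 0 ok, 1 fixed_region_mismatch, 2 product_overrun,
//         3 template/product ambiguity (non-ACGT), 4 low base quality.
// [[Rcpp::export]]
List cpp_locate_extract(CharacterVector merged, CharacterVector mqual,
                        std::string h5, std::string loop, std::string primer,
                        std::string rt, int template_len, int window,
                        int max_region_mm, int min_base_q) {
  int n = merged.size();
  IntegerVector status(n), tstart(n), pstart(n), plen(n);
  CharacterVector tpl(n), prd(n);
  int h5l = h5.size(), ll = loop.size(), pl = primer.size(), rtl = rt.size();
  for (int i = 0; i < n; ++i) {
    tpl[i] = NA_STRING; prd[i] = NA_STRING;
    tstart[i] = NA_INTEGER; pstart[i] = NA_INTEGER; plen[i] = NA_INTEGER;
    if (STRING_ELT(merged, i) == NA_STRING) { status[i] = 1; continue; }
    const char *s = CHAR(STRING_ELT(merged, i));
    const char *q = CHAR(STRING_ELT(mqual, i));
    int slen = LENGTH(STRING_ELT(merged, i));
    int mm;
    int o_h5 = best_offset(s, slen, h5.c_str(), h5l, 0, window, &mm);
    if (mm > max_region_mm) { status[i] = 1; continue; }
    int o_loop = best_offset(s, slen, loop.c_str(), ll,
                             o_h5 + h5l + template_len, window, &mm);
    if (mm > max_region_mm) { status[i] = 1; continue; }
    // substitution-only architecture: the template window must be exact
    if (o_loop - (o_h5 + h5l) != template_len) { status[i] = 1; continue; }
    int o_pr = best_offset(s, slen, primer.c_str(), pl, o_loop + ll, window, &mm);
    if (mm > max_region_mm || o_pr != o_loop + ll) { status[i] = 1; continue; }
    int o_rt = best_offset(s, slen, rt.c_str(), rtl, slen - rtl, window, &mm);
    if (mm > max_region_mm) { status[i] = 1; continue; }
    int t0 = o_h5 + h5l;          // template window [t0, t0 + template_len)
    int p0 = o_pr + pl;           // product window  [p0, o_rt)
    int L = o_rt - p0;
    if (L < 0) { status[i] = 1; continue; }
    tstart[i] = t0; pstart[i] = p0; plen[i] = L;
    if (L > template_len) { status[i] = 2; continue; }
    bool amb = false, lowq = false;
    for (int j = t0; j < t0 + template_len; ++j) {
      char c = s[j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') amb = true;
      if (q[j] - 33 < min_base_q) lowq = true;
    }
    for (int j = p0; j < p0 + L; ++j) {
      char c = s[j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T') amb = true;
      if (q[j] - 33 < min_base_q) lowq = true;
    }
    if (amb) { status[i] = 3; continue; }
    if (lowq) { status[i] = 4; continue; }
    status[i] = 0;
    tpl[i] = std::string(s + t0, template_len);
    prd[i] = std::string(s + p0, L);
  }
  return List::create(_["status"] = status, _["template"] = tpl,
                      _["product"] = prd, _["template_start"] = tstart,
                      _["product_start"] = pstart, _["product_len"] = plen);
}
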