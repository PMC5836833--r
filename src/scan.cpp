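#include <Rcpp.h>
using namespace Rcpp;

// Per-offset Match-style scores for one strand.
// seq: promoter encoded 0=A,1=C,2=G,3=T,4=N; w: 5 x L matrix of
// information-weighted frequency contributions (row 4 = N = column minimum).
// Returns (current - minsum)/(maxsum - minsum) at every offset, or 0
// everywhere when the matrix is fully degenerate (maxsum == minsum).
// [[Rcpp::export]]
NumericVector scan_scores_cpp(IntegerVector seq, NumericMatrix w,
                              double minsum, double maxsum) {
  const int n = seq.size(), L = w.ncol();
  if (n < L) return NumericVector(0);
  const int nout = n - L + 1;
  NumericVector out(nout);
  const double denom = maxsum - minsum;
  for (int o = 0; o < nout; ++o) {
    double cur = 0.0;
    for (int i = 0; i < L; ++i) cur += w(seq[o + i], i);
    double sc = (denom > 0.0) ? (cur - minsum) / denom : 0.0;
    out[o] = std::min(1.0, std::max(0.0, sc));
  }
  return out;
}

// Composite promoter scores for one module over a pre-scanned site table in
// CSR layout: prom_ptr (n_prom+1, 0-based offsets), and per-site pwm index,
// position and score, position-sorted within each promoter.
// member_of[p] maps a library pwm index to its member slot (-1 = not a member).
// Score of a promoter = max over candidate windows (anchored at each passing
// site) of sum over members of weight * best passing member site in window.
// [[Rcpp::export]]
NumericVector composite_scores_cpp(IntegerVector prom_ptr,
                                   IntegerVector site_pwm,
                                   NumericVector site_pos,
                                   NumericVector site_score,
                                   IntegerVector member_of,
                                   NumericVector member_cutoff,
                                   NumericVector member_weight,
                                   double window) {
  const int n_prom = prom_ptr.size() - 1;
  const int n_members = member_cutoff.size();
  NumericVector out(n_prom);
  std::vector<int> keep_m;
  std::vector<double> keep_pos, keep_score;
  std::vector<double> best(n_members);
  for (int pr = 0; pr < n_prom; ++pr) {
    keep_m.clear(); keep_pos.clear(); keep_score.clear();
    for (int s = prom_ptr[pr]; s < prom_ptr[pr + 1]; ++s) {
      const int m = member_of[site_pwm[s]];
      if (m >= 0 && site_score[s] >= member_cutoff[m]) {
        keep_m.push_back(m);
        keep_pos.push_back(site_pos[s]);
        keep_score.push_back(site_score[s]);
      }
    }
    const int k = (int)keep_m.size();
    double top = 0.0;
    for (int a = 0; a < k; ++a) {  // anchor window at each passing site
      const double lo = keep_pos[a], hi = keep_pos[a] + window;
      std::fill(best.begin(), best.end(), 0.0);
      for (int s = a; s < k; ++s) {  // positions sorted: start at anchor
        if (keep_pos[s] > hi) break;
        if (keep_pos[s] >= lo && keep_score[s] > best[keep_m[s]])
          best[keep_m[s]] = keep_score[s];
      }
      double tot = 0.0;
      for (int m = 0; m < n_members; ++m) tot += member_weight[m] * best[m];
      if (tot > top) top = tot;
    }
    out[pr] = top;
  }
  return out;
}

// Scan a whole promoter set with one PWM (both strands) in one call.
// seqs: concatenated encoded promoters; ptr: 0-based CSR offsets
// (n_prom+1); wf/wr: forward and reverse-complement 5 x L weight
// matrices with their min/max sums. Returns hits as parallel vectors;
// strand is 0 (+) or 1 (-), positions 0-based within each promoter.
// [[Rcpp::export]]
List scan_set_cpp(IntegerVector seqs, IntegerVector ptr,
                  NumericMatrix wf, double minf, double maxf,
                  NumericMatrix wr, double minr, double maxr,
                  double cutoff, bool both_strands) {
  const int n_prom = ptr.size() - 1, L = wf.ncol();
  std::vector<int> out_seq, out_pos, out_strand;
  std::vector<double> out_score;
  const double den_f = maxf - minf, den_r = maxr - minr;
  for (int pr = 0; pr < n_prom; ++pr) {
    const int lo = ptr[pr], n = ptr[pr + 1] - ptr[pr];
    if (n < L) continue;
    for (int o = 0; o <= n - L; ++o) {
      double cf = 0.0, cr = 0.0;
      for (int i = 0; i < L; ++i) {
        const int b = seqs[lo + o + i];
        cf += wf(b, i);
        cr += wr(b, i);
      }
      double sf = (den_f > 0.0) ? (cf - minf) / den_f : 0.0;
      sf = std::min(1.0, std::max(0.0, sf));
      if (sf >= cutoff) {
        out_seq.push_back(pr + 1); out_pos.push_back(o);
        out_strand.push_back(0); out_score.push_back(sf);
      }
      if (both_strands) {
        double sr = (den_r > 0.0) ? (cr - minr) / den_r : 0.0;
        sr = std::min(1.0, std::max(0.0, sr));
        if (sr >= cutoff) {
          out_seq.push_back(pr + 1); out_pos.push_back(o);
          out_strand.push_back(1); out_score.push_back(sr);
        }
      }
    }
  }
  return List::create(_["seq"] = wrap(out_seq), _["pos"] = wrap(out_pos),
                      _["strand"] = wrap(out_strand),
                      _["score"] = wrap(out_score));
}
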