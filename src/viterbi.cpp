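#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman-style) Viterbi over a plan-7 profile, in bits.
// sm, si: L x 20 match/insert emission scores, log2(p / background).
// tr: L x 7 transition scores log2(p), columns mm mi md im ii dm dd
//     (row k = transitions out of node k, 1-based).
// seq: residue column indices 1..20; 0 encodes X (scores 0 at any state).
// An alignment may begin and end at any match state; flanking residues are
// free, so the score is a maximum over all (start, end) envelopes.
// [[Rcpp::export(name = ".viterbi_local_cpp")]]
List viterbi_local_cpp(NumericMatrix sm, NumericMatrix si, NumericMatrix tr,
                       IntegerVector seq) {
  const int L = sm.nrow();
  const int n = seq.size();
  const double NEG = R_NegInf;
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;

  std::vector<double> Mprev(L, NEG), Iprev(L, NEG), Dprev(L, NEG);
  std::vector<double> Mcur(L), Icur(L), Dcur(L);
  std::vector<int> MprevS(L, 0), IprevS(L, 0), DprevS(L, 0);
  std::vector<int> McurS(L), IcurS(L), DcurS(L);

  double best = NEG;
  int bestStart = 0, bestEnd = 0;

  for (int i = 0; i < n; ++i) {
    int a = seq[i];  // 1..20 or 0 for X
    for (int k = 0; k < L; ++k) {
      double em = (a == 0) ? 0.0 : sm(k, a - 1);
      // M: fresh local start, or extend from node k-1 at position i-1
      double v = 0.0;            // fresh start
      int st = i + 1;            // 1-based start residue
      if (k > 0 && i > 0) {
        double c;
        c = Mprev[k - 1] + tr(k - 1, MM);
        if (c > v) { v = c; st = MprevS[k - 1]; }
        c = Iprev[k - 1] + tr(k - 1, IM);
        if (c > v) { v = c; st = IprevS[k - 1]; }
        c = Dprev[k - 1] + tr(k - 1, DM);
        if (c > v) { v = c; st = DprevS[k - 1]; }
      }
      Mcur[k] = em + v;
      McurS[k] = st;
      if (Mcur[k] > best) { best = Mcur[k]; bestStart = McurS[k]; bestEnd = i + 1; }
      // I: insert at node k, consumes residue i
      double iv = NEG; int ist = 0;
      if (i > 0) {
        double c = Mprev[k] + tr(k, MI);
        if (c > iv) { iv = c; ist = MprevS[k]; }
        c = Iprev[k] + tr(k, II);
        if (c > iv) { iv = c; ist = IprevS[k]; }
      }
      double iem = (a == 0) ? 0.0 : si(k, a - 1);
      Icur[k] = (iv == NEG) ? NEG : iem + iv;
      IcurS[k] = ist;
      // D: delete node k, no residue consumed (same column i)
      double dv = NEG; int dst = 0;
      if (k > 0) {
        double c = Mcur[k - 1] + tr(k - 1, MD);
        if (c > dv) { dv = c; dst = McurS[k - 1]; }
        c = Dcur[k - 1] + tr(k - 1, DD);
        if (c > dv) { dv = c; dst = DcurS[k - 1]; }
      }
      Dcur[k] = dv;
      DcurS[k] = dst;
    }
    std::swap(Mprev, Mcur); std::swap(Iprev, Icur); std::swap(Dprev, Dcur);
    std::swap(MprevS, McurS); std::swap(IprevS, IcurS); std::swap(DprevS, DcurS);
  }
  return List::create(_["bit_score"] = best,
                      _["ali_start"] = bestStart,
                      _["ali_end"] = bestEnd);
}
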