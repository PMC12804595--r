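"""Hashed molecular fingerprints over a SMILES list (RDKit backend).

Reads one SMILES per line, writes one TSV line per input:
  ok(0/1) <TAB> comma-separated index:value pairs of the nonzero bits.
Row order is preserved; unparseable SMILES get ok=0 and empty bits.
"""
import argparse

from rdkit import Chem, RDLogger
from rdkit.Avalon import pyAvalonTools
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def fingerprint(mol, view, width, radius):
    if view == "avalon":
        fp = pyAvalonTools.GetAvalonFP(mol, nBits=width)
        return {b: 1 for b in fp.GetOnBits()}
    if view == "morgan":
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=width)
        return {b: 1 for b in gen.GetFingerprint(mol).GetOnBits()}
    if view == "atompair":
        gen = rdFingerprintGenerator.GetAtomPairGenerator(fpSize=width)
        return dict(gen.GetCountFingerprint(mol).GetNonzeroElements())
    raise SystemExit(f"unknown view: {view}")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--view", required=True, choices=["avalon", "morgan", "atompair"])
    ap.add_argument("--width", type=int, default=1024)
    ap.add_argument("--radius", type=int, default=2)
    ap.add_argument("--in", dest="infile", required=True)
    ap.add_argument("--out", dest="outfile", required=True)
    args = ap.parse_args()

    with open(args.infile) as fh:
        smiles = [line.rstrip("\n") for line in fh]

    with open(args.outfile, "w") as out:
        for smi in smiles:
            mol = Chem.MolFromSmiles(smi) if smi else None
            if mol is None:
                out.write("0\t\n")
                continue
            bits = fingerprint(mol, args.view, args.width, args.radius)
            enc = ",".join(f"{k}:{v}" for k, v in sorted(bits.items()))
            out.write(f"1\t{enc}\n")


if __name__ == "__main__":
    main()
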