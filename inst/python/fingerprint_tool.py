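#!/usr/bin/env python
"""RDKit backend for fpresample.

Subcommands (last positional argument is always an input file):
  validate <tsv>   -- lines "id\tsmiles"; prints "id\t1" (parseable) / "id\t0"
  fps <tsv>        -- lines "id\tsmiles"; prints "id\t<bitstring>";
                      exits 1 naming the first unparseable compound
  sdf2table <sdf>  -- prints "id\tsmiles\tlabel" per parseable molecule
"""
import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import MACCSkeys
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def read_pairs(path):
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line.strip():
                continue
            ident, smiles = line.split("\t", 1)
            yield ident, smiles


def cmd_validate(args):
    for ident, smiles in read_pairs(args.input):
        mol = Chem.MolFromSmiles(smiles)
        print(f"{ident}\t{0 if mol is None else 1}")


def fingerprint(mol, descriptor, radius, bits):
    if descriptor == "maccs":
        fp = MACCSkeys.GenMACCSKeys(mol)
        # RDKit emits 167 positions with index 0 unused: drop it -> 166 keys
        return "".join("1" if fp.GetBit(i) else "0" for i in range(1, 167))
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=bits)
    fp = gen.GetFingerprint(mol)
    return fp.ToBitString()


def cmd_fps(args):
    for ident, smiles in read_pairs(args.input):
        mol = Chem.MolFromSmiles(smiles)
        if mol is None:
            sys.stderr.write(f"unparseable SMILES for compound '{ident}'\n")
            sys.exit(1)
        print(f"{ident}\t{fingerprint(mol, args.descriptor, args.radius, args.bits)}")


def cmd_sdf2table(args):
    supplier = Chem.SDMolSupplier(args.input, sanitize=True)
    for i, mol in enumerate(supplier):
        if mol is None:
            continue
        if mol.HasProp(args.id_field):
            ident = mol.GetProp(args.id_field)
        elif mol.HasProp("_Name") and mol.GetProp("_Name").strip():
            ident = mol.GetProp("_Name").strip()
        else:
            ident = f"mol{i + 1}"
        if not mol.HasProp(args.label_field):
            sys.stderr.write(
                f"molecule '{ident}' lacks label property '{args.label_field}'\n")
            sys.exit(1)
        print(f"{ident}\t{Chem.MolToSmiles(mol)}\t{mol.GetProp(args.label_field)}")


def main():
    parser = argparse.ArgumentParser(prog="fingerprint_tool")
    sub = parser.add_subparsers(dest="cmd", required=True)

    p = sub.add_parser("validate")
    p.add_argument("input")
    p.set_defaults(func=cmd_validate)

    p = sub.add_parser("fps")
    p.add_argument("--descriptor", choices=["maccs", "morgan"], required=True)
    p.add_argument("--radius", type=int, default=2)
    p.add_argument("--bits", type=int, default=2048)
    p.add_argument("input")
    p.set_defaults(func=cmd_fps)

    p = sub.add_parser("sdf2table")
    p.add_argument("--id-field", default="id")
    p.add_argument("--label-field", default="label")
    p.add_argument("input")
    p.set_defaults(func=cmd_sdf2table)

    args = parser.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
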