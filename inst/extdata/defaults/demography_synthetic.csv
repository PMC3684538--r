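year,wra,prop_in_union,e0
1995,4500000,0.7,56
1996,4626000,0.7,56.3
1997,4755528,0.7,56.6
1998,4888683,0.7,56.9
1999,5025566,0.7,57.2
2000,5166282,0.7,57.5
2001,5310938,0.7,57.8
2002,5459644,0.7,58.1
2003,5612514,0.7,58.4
2004,5769664,0.7,58.7
2005,5931215,0.7,59
2006,6097289,0.7,59.3
2007,6268013,0.7,59.6
2008,6443517,0.7,59.9
2009,6623936,0.7,60.2
2010,6809406,0.7,60.5
2011,7000069,0.7,60.8
2012,7196071,0.7,61.1
2013,7397561,0.7,61.4
2014,7604693,0.7,61.7
2015,7817625,0.7,62
2016,8036518,0.7,62.3
2017,8261541,0.7,62.6
2018,8492864,0.7,62.9
2019,8730664,0.7,63.2
2020,8975122,0.7,63.5
2021,9226426,0.7,63.8
2022,9484766,0.7,64.1
2023,9750339,0.7,64.4
2024,10023349,0.7,64.7
2025,10304002,0.7,65
2026,10592515,0.7,65.3
2027,10889105,0.7,65.6
2028,11194000,0.7,65.9
2029,11507432,0.7,66.2
2030,11829640,0.7,66.5
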