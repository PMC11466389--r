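sewershed,county,sewershed_population,county_population,pct_monitored
Laurinburg,Scotland,15527,34823,45
Tuckaseigee,Jackson,13296,43109,31
Marion,McDowell,8459,45756,18
Beaufort,Carteret,3500,69473,5
Roanoke Rapids,Halifax,14320,69493,21
City of Wilson,Wilson,49384,81801,60
Chapel Hill-Carrboro,Orange,78141,148476,53
Greenville,Pitt,89616,180742,50
Wilmington City,New Hanover,58361,234473,25
New Hanover County (North),New Hanover,67743,234473,29
South Durham,Durham,108105,321488,34
Fayetteville-Rockfish Creek,Cumberland,151589,335509,45
MSD of Buncombe County,Buncombe,173000,378608,46
Winston Salem-Salem,Forsyth,178000,382295,47
Jacksonville,Onslow,41819,204576,20
"Greensboro, North Buffalo",Guilford,135821,537174,25
Charlotte 1,Mecklenburg,68685,1110356,6
Charlotte 2,Mecklenburg,182501,1110356,16
Charlotte 3,Mecklenburg,120000,1110356,11
Raleigh,Wake,550000,1111761,49
Raleigh 2,Wake,37020,1111761,3
Raleigh 3,Wake,7648,1111761,1
Cary 1,Wake,84189,1111761,8
Cary 2,Wake,74331,1111761,7
Cary 3,Wake,75886,1111761,7
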