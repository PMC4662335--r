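area,latitude,n_wetlands,years
Acadia National Park,44.4,28,2004-2007;2009-2013
Cape Cod National Seashore,41.9,30,2004-2009;2011-2013
Canaan Valley National Wildlife Refuge and State Park,39.1,111,2004-2013
Delaware Water Gap National Recreation Area,41.2,45,2005-2006
Eastern Massachusetts National Wildlife Refuge,42.5,39,2004-2012
Erie National Wildlife Refuge,41.7,19,2004-2007;2009-2013
Gettysburg National Historic Park,39.8,20,2005-2007;2012
Great Swamp National Wildlife Refuge,40.7,95,2004-2013
Iroquois National Wildlife Refuge,43.1,20,2005-2007;2012
Moosehorn National Wildlife Refuge,45.1,43,2004-2007;2010-2011
Patuxent Research Refuge,39.1,100,2004-2013
Rachel Carson National Wildlife Refuge,43.3,12,2004-2013
Rock Creek Park,39.0,11,2005-2013
Walkill River National Wildlife Refuge,41.2,32,2004-2006;2010-2013
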